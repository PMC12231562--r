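# Mutation-frequency statistics, per-plant averaging, spectrum ratios, and
# TSS-relative profiles.
#
# The headline frequency statistic is
#   f = (total events / n lines) / L_ref / dose      [events / bp / Gy]
# reported scaled by 1e10. With the five nuclear chromosomes of the TAIR10
# Arabidopsis assembly, L_ref = 119,146,348 bp.

#' TAIR10 nuclear genome length (bp)
#'
#' Sum of the five nuclear chromosome lengths of the Arabidopsis thaliana
#' TAIR10 assembly, the reference length used by the frequency statistic.
#' @export
TAIR10_GENOME_LENGTH <- 119146348

#' Mutation frequency per bp per Gy
#'
#' `(event_count_total / n_lines) / genome_length / dose`. Use
#' `scale = 1e10` to obtain the conventional reporting units of
#' \eqn{10^{-10}} mutations/bp/Gy.
#'
#' @param event_count_total Total events across the genotype's lines.
#' @param n_lines Number of sequenced lines.
#' @param genome_length Reference genome length in bp.
#' @param dose Dose in Gy (> 0; unirradiated controls are reported as
#'   counts, not frequencies).
#' @param scale Multiplier applied to the result (default 1 = raw
#'   per-bp-per-Gy).
#' @return Numeric frequency.
#' @export
mutation_frequency <- function(event_count_total, n_lines, genome_length,
                               dose, scale = 1) {
  stopifnot(n_lines >= 1, genome_length >= 1)
  if (any(dose <= 0)) {
    stop("dose must be > 0 Gy; report unirradiated controls as counts")
  }
  (event_count_total / n_lines) / genome_length / dose * scale
}

#' Fold change between two frequencies
#'
#' @param freq_a,freq_b Frequencies on the same scale; `freq_b > 0`.
#' @return `freq_a / freq_b`.
#' @export
fold_change <- function(freq_a, freq_b) {
  if (any(freq_b <= 0)) stop("fold change undefined for freq_b <= 0")
  freq_a / freq_b
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

# per-line ratio helper: NA when the denominator is zero
safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Per-plant mutation spectrum summary
#'
#' Computes, per line: event counts by category, category proportions,
#' Ts/Tv, Ins/Dels and SBS/InDels ratios; then per genotype: mean of the
#' per-plant proportions and ratios (+- SEM, n = lines of the genotype) and
#' per-bp-per-Gy frequencies from genotype totals. Lines whose ratio
#' denominator is zero are excluded from that ratio's mean.
#'
#' @param events Event data.frame from [classify_events()] (optionally with
#'   SV events appended).
#' @param meta Line metadata with columns `line_id`, `genotype`, `dose`.
#' @param genome_length Reference length in bp used by the frequency
#'   statistic (default the TAIR10 constant).
#' @return `list(per_line, per_genotype, frequencies)`; `frequencies` holds
#'   per-category and total frequencies scaled by 1e10.
#' @export
per_plant_summary <- function(events, meta,
                              genome_length = TAIR10_GENOME_LENGTH) {
  stopifnot(all(c("line_id", "genotype", "dose") %in% names(meta)))
  unknown <- setdiff(unique(events$line_id), meta$line_id)
  if (length(unknown)) {
    stop("events reference unknown line(s): ",
         paste(unknown, collapse = ", "))
  }
  cats <- setdiff(MUTATION_CATEGORIES, "SV")
  if (any(events$category == "SV")) cats <- MUTATION_CATEGORIES
  counts <- table(factor(events$line_id, levels = meta$line_id),
                  factor(events$category, levels = cats))
  tot <- rowSums(counts)
  prop <- counts / pmax(tot, 1L)

  ts <- tapply(is_transition(events$sbs_class[events$category == "SBS"]),
               factor(events$line_id[events$category == "SBS"],
                      levels = meta$line_id), sum)
  tv <- tapply(!is_transition(events$sbs_class[events$category == "SBS"]),
               factor(events$line_id[events$category == "SBS"],
                      levels = meta$line_id), sum)
  ts[is.na(ts)] <- 0; tv[is.na(tv)] <- 0
  ins <- counts[, "ins1"] + counts[, "ins_ge2"]
  del <- counts[, "del1"] + counts[, "del_ge2"]
  sbs <- counts[, "SBS"]
  indel <- ins + del

  per_line <- data.frame(
    line_id = meta$line_id, genotype = meta$genotype, dose = meta$dose,
    n_events = as.integer(tot), as.data.frame.matrix(counts),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (ct in cats) per_line[[paste0("prop_", ct)]] <- prop[, ct]
  per_line$ts_tv <- safe_ratio(as.numeric(ts), as.numeric(tv))
  per_line$ins_dels <- safe_ratio(as.numeric(ins), as.numeric(del))
  per_line$sbs_indels <- safe_ratio(as.numeric(sbs), as.numeric(indel))

  gsplit <- split(per_line, per_line$genotype)
  empty_geno <- vapply(gsplit, function(d) sum(d$n_events) == 0, logical(1))
  if (any(empty_geno)) {
    warning("genotype(s) without events: ",
            paste(names(gsplit)[empty_geno], collapse = ", "))
  }
  per_genotype <- do.call(rbind, lapply(gsplit, function(d) {
    use <- d[d$n_events > 0, , drop = FALSE]
    out <- data.frame(genotype = d$genotype[1], n_lines = nrow(d),
                      dose = d$dose[1], total_events = sum(d$n_events),
                      mean_events_per_plant = mean(d$n_events),
                      stringsAsFactors = FALSE)
    for (ct in cats) {
      out[[paste0("mean_prop_", ct)]] <- mean(use[[paste0("prop_", ct)]])
      out[[paste0("sem_prop_", ct)]] <- sem(use[[paste0("prop_", ct)]])
    }
    for (rt in c("ts_tv", "ins_dels", "sbs_indels")) {
      v <- use[[rt]][is.finite(use[[rt]])]
      out[[paste0("mean_", rt)]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0("sem_", rt)]] <- if (length(v) > 1) sem(v) else NA_real_
    }
    out
  }))
  rownames(per_genotype) <- NULL

  frequencies <- do.call(rbind, lapply(gsplit, function(d) {
    tot_by_cat <- colSums(counts[d$line_id, , drop = FALSE])
    out <- data.frame(genotype = d$genotype[1], n_lines = nrow(d),
                      dose = d$dose[1], stringsAsFactors = FALSE)
    for (ct in cats) {
      out[[ct]] <- mutation_frequency(tot_by_cat[[ct]], nrow(d),
                                      genome_length, d$dose[1],
                                      scale = 1e10)
    }
    out$total <- mutation_frequency(sum(tot_by_cat), nrow(d),
                                    genome_length, d$dose[1], scale = 1e10)
    out
  }))
  rownames(frequencies) <- NULL

  list(per_line = per_line, per_genotype = per_genotype,
       frequencies = frequencies)
}

#' TSS-relative mutation profile
#'
#' For every non-intergenic annotated event, the signed distance to the
#' transcription start site of its annotated gene, measured along the
#' direction of transcription (negative = upstream of the TSS), binned over
#' `[-window, +window]`.
#'
#' @param annotated Events with `gene_id`/`subclass` columns from
#'   [annotate_impact()].
#' @param models Gene models from [read_gene_models()].
#' @param meta Optional line metadata; when given, counts are reported per
#'   genotype.
#' @param window Half-width of the profile in bp (default 10000).
#' @param bin Bin width in bp (default 1000).
#' @return `list(distances, profile)`: per-event signed distances and the
#'   binned counts (columns `bin_start`, `bin_mid`, `bin_end`, `genotype`,
#'   `count`).
#' @export
tss_profile <- function(annotated, models, meta = NULL, window = 10000L,
                        bin = 1000L) {
  keep <- annotated$subclass != "intergenic" & !is.na(annotated$gene_id)
  ev <- annotated[keep, , drop = FALSE]
  gi <- match(ev$gene_id, models$gene_id)
  d <- ifelse(models$strand[gi] == "-",
              models$tss[gi] - ev$start,
              ev$start - models$tss[gi])
  dist <- data.frame(line_id = ev$line_id, gene_id = ev$gene_id,
                     distance = d, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    dist$genotype <- meta$genotype[match(dist$line_id, meta$line_id)]
  } else {
    dist$genotype <- "all"
  }
  inwin <- dist[abs(dist$distance) <= window, , drop = FALSE]
  breaks <- seq(-window, window, by = bin)
  profile <- do.call(rbind, lapply(split(inwin, inwin$genotype),
                                   function(g) {
    h <- graphics::hist(g$distance, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)
    data.frame(genotype = g$genotype[1],
               bin_start = utils::head(breaks, -1L),
               bin_end = breaks[-1L],
               bin_mid = (utils::head(breaks, -1L) + breaks[-1L]) / 2,
               count = h$counts, stringsAsFactors = FALSE)
  }))
  rownames(profile) <- NULL
  list(distances = dist, profile = profile)
}
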