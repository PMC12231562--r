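# Lightweight variant-effect tiering.
#
# Subclasses map to four impact tiers:
#   HIGH     - frameshift, stop_gained, stop_lost, start_lost,
#              splice_donor, splice_acceptor
#   MODERATE - missense, inframe_indel, utr5, utr3
#   LOW      - synonymous, intron
#   MODIFIER - upstream, downstream, intergenic
# Note UTR variants sit in MODERATE and intron variants in LOW in this map
# (deliberately; this is the tiering the downstream summaries assume).

IMPACT_TIER_MAP <- c(
  frameshift = "HIGH", stop_gained = "HIGH", stop_lost = "HIGH",
  start_lost = "HIGH", splice_donor = "HIGH", splice_acceptor = "HIGH",
  missense = "MODERATE", inframe_indel = "MODERATE", utr5 = "MODERATE",
  utr3 = "MODERATE",
  synonymous = "LOW", intron = "LOW",
  upstream = "MODIFIER", downstream = "MODIFIER", intergenic = "MODIFIER"
)

IMPACT_TIERS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

# severity ranking used when a variant touches several features/genes
IMPACT_SEVERITY <- names(IMPACT_TIER_MAP)

#' Impact tier of a subclass
#'
#' @param subclass Subclass labels (see `IMPACT_TIER_MAP`).
#' @return Tier labels among HIGH, MODERATE, LOW, MODIFIER.
#' @export
impact_tier <- function(subclass) {
  bad <- setdiff(subclass, names(IMPACT_TIER_MAP))
  if (length(bad)) stop("unknown impact subclass: ",
                        paste(bad, collapse = ", "))
  unname(IMPACT_TIER_MAP[subclass])
}

# genomic positions of a gene's CDS in transcription order (5'->3' of the
# mRNA), after applying the phase offset of the first CDS segment
cds_positions <- function(model) {
  cd <- model$cds[[1]]
  if (is.null(cd) || nrow(cd) == 0L) return(integer(0))
  minus <- identical(model$strand, "-")
  posl <- lapply(seq_len(nrow(cd)), function(j) {
    p <- seq(cd$start[j], cd$end[j])
    if (minus) rev(p) else p
  })
  pos <- unlist(posl)
  off <- cd$phase[1L]
  if (off > 0L) pos <- pos[-seq_len(off)]
  pos
}

# intron intervals of a gene in genomic coordinates, with donor/acceptor
# 2-bp windows oriented by strand (donor = intron end adjacent to the
# upstream exon in transcription direction)
intron_features <- function(model) {
  ex <- model$exons[[1]]
  if (nrow(ex) < 2L) {
    return(data.frame(start = integer(0), end = integer(0),
                      donor_start = integer(0), donor_end = integer(0),
                      acceptor_start = integer(0),
                      acceptor_end = integer(0)))
  }
  exs <- ex[order(ex$start), , drop = FALSE]
  istart <- exs$end[-nrow(exs)] + 1L
  iend <- exs$start[-1L] - 1L
  keep <- istart <= iend
  istart <- istart[keep]; iend <- iend[keep]
  minus <- identical(model$strand, "-")
  if (!minus) {
    data.frame(start = istart, end = iend,
               donor_start = istart, donor_end = pmin(istart + 1L, iend),
               acceptor_start = pmax(iend - 1L, istart),
               acceptor_end = iend)
  } else {
    data.frame(start = istart, end = iend,
               donor_start = pmax(iend - 1L, istart), donor_end = iend,
               acceptor_start = istart,
               acceptor_end = pmin(istart + 1L, iend))
  }
}

overlaps <- function(a1, a2, b1, b2) a1 <= b2 & a2 >= b1

# subclass of one normalized simple call (contig,pos,ref,alt) w.r.t. one
# gene model; NA when the call is outside gene span + flank
call_subclass_for_gene <- function(contig, pos, ref, alt, model, genome,
                                   flank) {
  if (contig != model$contig) return(NA_character_)
  nr <- nchar(ref); na <- nchar(alt)
  is_indel <- nr != na
  if (is_indel) {
    geo <- indel_geometry(contig, pos, ref, alt)
    if (geo$type == "del") {
      a <- geo$jstart; b <- geo$jend
    } else {
      a <- geo$ins_point; b <- geo$ins_point + 1L
    }
  } else {
    a <- pos; b <- pos + nr - 1L
  }

  if (!overlaps(a, b, model$start - flank, model$end + flank)) {
    return(NA_character_)
  }
  if (!overlaps(a, b, model$start, model$end)) {
    upstream_side <- if (identical(model$strand, "-"))
      a > model$end else b < model$start
    return(if (upstream_side) "upstream" else "downstream")
  }

  intr <- intron_features(model)
  if (nrow(intr)) {
    if (any(overlaps(a, b, intr$donor_start, intr$donor_end))) {
      return("splice_donor")
    }
    if (any(overlaps(a, b, intr$acceptor_start, intr$acceptor_end))) {
      return("splice_acceptor")
    }
  }

  cd <- model$cds[[1]]
  in_cds <- nrow(cd) > 0L && any(overlaps(a, b, cd$start, cd$end))
  if (in_cds) {
    if (is_indel) {
      len <- na - nr
      return(if (abs(len) %% 3L != 0L) "frameshift" else "inframe_indel")
    }
    return(sbs_coding_subclass(contig, pos, ref, alt, model, genome))
  }

  ex <- model$exons[[1]]
  in_exon <- any(overlaps(a, b, ex$start, ex$end))
  if (in_exon) {
    if (nrow(cd) == 0L) return("intron")   # non-coding gene: conservative
    minus <- identical(model$strand, "-")
    cds_lo <- min(cd$start); cds_hi <- max(cd$end)
    if (b < cds_lo) return(if (minus) "utr3" else "utr5")
    if (a > cds_hi) return(if (minus) "utr5" else "utr3")
    return("intron")                       # straddles; should not happen
  }
  "intron"
}

# coding SBS: translate the affected codon with and without the variant
sbs_coding_subclass <- function(contig, pos, ref, alt, model, genome) {
  cdspos <- cds_positions(model)
  idx <- match(pos, cdspos)
  if (is.na(idx)) return("intron")         # phase-trimmed leading bases
  minus <- identical(model$strand, "-")
  codon_i <- (idx - 1L) %/% 3L
  cpos <- cdspos[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  if (anyNA(cpos)) return("missense")      # truncated trailing codon
  base_at <- function(p) substr(genome[[contig]], p, p)
  bases <- vapply(cpos, base_at, character(1))
  if (minus) bases <- unname(DNA_COMPLEMENT[bases])
  ref_codon <- paste(bases, collapse = "")
  k <- which(cpos == pos)
  alt_b <- if (minus) unname(DNA_COMPLEMENT[alt]) else alt
  bases[k] <- alt_b
  alt_codon <- paste(bases, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon]); alt_aa <- unname(gc[alt_codon])
  if (is.na(ref_aa) || is.na(alt_aa)) return("missense")
  if (codon_i == 0L && ref_aa == "M" && alt_aa != "M") return("start_lost")
  if (ref_aa != "*" && alt_aa == "*") return("stop_gained")
  if (ref_aa == "*" && alt_aa != "*") return("stop_lost")
  if (ref_aa == alt_aa) return("synonymous")
  "missense"
}

#' Annotate events with impact subclass and tier
#'
#' Each event is assigned the most severe subclass over all overlapping gene
#' models (severity ranking: frameshift > stop_gained > stop_lost >
#' start_lost > splice_donor > splice_acceptor > missense > inframe_indel >
#' utr5 > utr3 > synonymous > intron > upstream > downstream), falling back
#' to `intergenic` beyond `flank` bp of every gene. Complex events take the
#' most severe subclass among their member calls.
#'
#' @param events Event data.frame from [classify_events()].
#' @param models Gene models from [read_gene_models()].
#' @param genome Named character vector of contig sequences.
#' @param flank Upstream/downstream window in bp (default 5000).
#' @return `events` with added columns `gene_id`, `subclass`, `tier`.
#' @export
annotate_impact <- function(events, models, genome, flank = 5000L) {
  n <- nrow(events)
  gene_id <- rep(NA_character_, n)
  subclass <- rep("intergenic", n)
  for (i in seq_len(n)) {
    if (identical(events$category[i], "complex")) {
      mem <- events$members[[i]]
      parts <- lapply(seq_len(nrow(mem)), function(j)
        best_subclass(mem$contig[j], mem$pos[j], mem$ref[j], mem$alt[j],
                      models, genome, flank))
    } else {
      parts <- list(best_subclass(events$contig[i], events$start[i],
                                  events$ref[i], events$alt[i],
                                  models, genome, flank))
    }
    ranks <- vapply(parts, function(p) match(p$subclass, IMPACT_SEVERITY),
                    numeric(1))
    best <- parts[[which.min(ranks)]]
    gene_id[i] <- best$gene_id
    subclass[i] <- best$subclass
  }
  events$gene_id <- gene_id
  events$subclass <- subclass
  events$tier <- impact_tier(subclass)
  events
}

# most severe (gene_id, subclass) of one simple call over all gene models
best_subclass <- function(contig, pos, ref, alt, models, genome, flank) {
  best <- list(gene_id = NA_character_, subclass = "intergenic")
  best_rank <- match("intergenic", IMPACT_SEVERITY)
  for (g in seq_len(nrow(models))) {
    sc <- call_subclass_for_gene(contig, pos, ref, alt,
                                 models[g, , drop = FALSE], genome, flank)
    if (is.na(sc)) next
    r <- match(sc, IMPACT_SEVERITY)
    if (r < best_rank) {
      best <- list(gene_id = models$gene_id[g], subclass = sc)
      best_rank <- r
    }
  }
  best
}

#' Per-line and per-genotype impact-tier proportions
#'
#' Tier proportions are computed per line, then averaged across the lines of
#' each genotype (per-plant averaging), with the standard error of that
#' mean. The mean frameshift count per plant is reported alongside.
#'
#' @param annotated Event data.frame with `subclass`/`tier` columns (from
#'   [annotate_impact()]).
#' @param meta Line metadata data.frame with `line_id` and `genotype`
#'   columns.
#' @return `list(per_line, per_genotype, subclass_counts)`.
#' @export
impact_proportions <- function(annotated, meta) {
  lines <- meta$line_id
  counts <- table(factor(annotated$line_id, levels = lines),
                  factor(annotated$tier, levels = IMPACT_TIERS))
  tot <- rowSums(counts)
  empty <- tot == 0
  if (any(empty)) {
    warning("line(s) with no annotated events excluded: ",
            paste(lines[empty], collapse = ", "))
  }
  prop <- counts / pmax(tot, 1L)
  fs <- table(factor(annotated$line_id[annotated$subclass == "frameshift"],
                     levels = lines))
  per_line <- data.frame(line_id = lines,
                         genotype = meta$genotype[match(lines,
                                                        meta$line_id)],
                         n_events = as.integer(tot),
                         as.data.frame.matrix(prop),
                         frameshift_count = as.integer(fs),
                         check.names = FALSE, stringsAsFactors = FALSE)
  use <- per_line[!empty, , drop = FALSE]
  per_genotype <- do.call(rbind, lapply(split(use, use$genotype),
                                        function(d) {
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    out <- data.frame(genotype = d$genotype[1], n_lines = nrow(d),
                      stringsAsFactors = FALSE)
    for (t in IMPACT_TIERS) {
      out[[paste0("mean_", t)]] <- mean(d[[t]])
      out[[paste0("sem_", t)]] <- sem(d[[t]])
    }
    out$mean_frameshift_per_plant <- mean(d$frameshift_count)
    out
  }))
  rownames(per_genotype) <- NULL
  subclass_counts <- as.data.frame(
    table(genotype = meta$genotype[match(annotated$line_id, meta$line_id)],
          subclass = annotated$subclass),
    stringsAsFactors = FALSE)
  list(per_line = per_line, per_genotype = per_genotype,
       subclass_counts = subclass_counts)
}
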