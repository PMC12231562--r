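# Synthetic genome / gene-model / mutation-call generation.
#
# The generator emits a random genome seeded with homopolymer runs and
# perfect tandem repeats, non-overlapping gene models, and per-line variant
# calls drawn from a genotype profile (category mix, SBS class mix, InDel
# length distribution, microhomology-class mix, TSS-proximal placement
# bias), together with a ground-truth record per emitted event. Everything
# is reproducible from a seed.

#' Genotype mutation profile
#'
#' @param name Genotype label.
#' @param dose Dose in Gy.
#' @param n_lines Number of sequenced lines.
#' @param mean_events_per_line Poisson mean of events per line.
#' @param category_probs Named probabilities over
#'   `SBS, del1, ins1, del_ge2, ins_ge2, complex` (sums to 1; SVs are not
#'   generated by the small-variant simulator).
#' @param sbs_class_probs Named probabilities over the six SBS classes.
#' @param indel_ge2_bin_probs Probabilities over the `2-10`, `11-30`, `>30`
#'   length bins for `>= 2` bp InDels.
#' @param indel_max_len Hard cap on InDel length in bp (`NA` = none); a cap
#'   of 30 forces zero mass on the `>30` bin.
#' @param mh_class_probs Named probabilities over
#'   `homopoly, polynucleotide_repeat, independent`.
#' @param tss_bias `list(weight, scale)`: fraction of placements drawn
#'   TSS-proximally and the exponential decay scale in bp.
#' @return A validated `genotype_profile` list.
#' @export
genotype_profile <- function(name, dose, n_lines, mean_events_per_line,
                             category_probs, sbs_class_probs,
                             indel_ge2_bin_probs = c(`2-10` = 0.8,
                                                     `11-30` = 0.15,
                                                     `>30` = 0.05),
                             indel_max_len = NA,
                             mh_class_probs = c(homopoly = 1 / 3,
                                                polynucleotide_repeat = 1 / 3,
                                                independent = 1 / 3),
                             tss_bias = list(weight = 0.6, scale = 3000)) {
  cat_names <- c("SBS", "del1", "ins1", "del_ge2", "ins_ge2", "complex")
  mh_names <- c("homopoly", "polynucleotide_repeat", "independent")
  bin_names <- c("2-10", "11-30", ">30")
  stopifnot(setequal(names(category_probs), cat_names),
            setequal(names(sbs_class_probs), SBS_CLASSES),
            setequal(names(indel_ge2_bin_probs), bin_names),
            setequal(names(mh_class_probs), mh_names),
            abs(sum(category_probs) - 1) < 1e-6,
            abs(sum(sbs_class_probs) - 1) < 1e-6,
            abs(sum(indel_ge2_bin_probs) - 1) < 1e-6,
            abs(sum(mh_class_probs) - 1) < 1e-6,
            dose > 0, n_lines >= 1, mean_events_per_line > 0)
  if (!is.na(indel_max_len) && indel_max_len <= 30 &&
      indel_ge2_bin_probs[[">30"]] > 0) {
    stop("indel_max_len <= 30 requires zero probability on the >30 bin")
  }
  structure(list(name = name, dose = dose, n_lines = as.integer(n_lines),
                 mean_events_per_line = mean_events_per_line,
                 category_probs = category_probs[cat_names],
                 sbs_class_probs = sbs_class_probs[SBS_CLASSES],
                 indel_ge2_bin_probs = indel_ge2_bin_probs[bin_names],
                 indel_max_len = indel_max_len,
                 mh_class_probs = mh_class_probs[mh_names],
                 tss_bias = tss_bias),
            class = "genotype_profile")
}

#' Packaged genotype profiles
#'
#' The three built-in profiles emulate the observed mutation spectra of the
#' CIB-irradiated genotypes: wild type at 200 Gy (10 lines, 31.8 events per
#' line), the POLQ-deficient teb-8 at 100 Gy (11 lines, 224/11 events per
#' line, no InDel above 30 bp) and the C-NHEJ-deficient lig4-4 at 100 Gy
#' (14 lines, 192/14 events per line, 67.62% of InDels
#' polynucleotide-repeat dependent). Category mixes follow the published
#' per-genotype proportions; parameters not printed are derived in the
#' methods vignette.
#'
#' @return Named list of three [genotype_profile()] objects
#'   (`WT`, `teb-8`, `lig4-4`).
#' @export
packaged_profiles <- function() {
  list(
    "WT" = genotype_profile(
      name = "WT", dose = 200, n_lines = 10,
      mean_events_per_line = 318 / 10,
      category_probs = c(SBS = 0.7296, del1 = 0.1038, ins1 = 0.0377,
                         del_ge2 = 0.1006, ins_ge2 = 0.0220,
                         complex = 0.0063),
      sbs_class_probs = c(`A/T>G/C` = 0.25, `G/C>A/T` = 0.25,
                          `A/T>T/A` = 0.22, `A/T>C/G` = 0.10,
                          `G/C>T/A` = 0.12, `G/C>C/G` = 0.06),
      indel_ge2_bin_probs = c(`2-10` = 0.80, `11-30` = 0.15, `>30` = 0.05),
      indel_max_len = NA,
      mh_class_probs = c(homopoly = 0.242,
                         polynucleotide_repeat = 0.258,
                         independent = 0.500)),
    "teb-8" = genotype_profile(
      name = "teb-8", dose = 100, n_lines = 11,
      mean_events_per_line = 224 / 11,
      category_probs = c(SBS = 0.6518, del1 = 0.1652, ins1 = 0.0403,
                         del_ge2 = 0.0800, ins_ge2 = 0.0182,
                         complex = 0.0445),
      sbs_class_probs = c(`A/T>G/C` = 0.20, `G/C>A/T` = 0.38,
                          `A/T>T/A` = 0.12, `A/T>C/G` = 0.08,
                          `G/C>T/A` = 0.14, `G/C>C/G` = 0.08),
      indel_ge2_bin_probs = c(`2-10` = 0.85, `11-30` = 0.15, `>30` = 0),
      indel_max_len = 30,
      mh_class_probs = c(homopoly = 0.366,
                         polynucleotide_repeat = 0.134,
                         independent = 0.500)),
    "lig4-4" = genotype_profile(
      name = "lig4-4", dose = 100, n_lines = 14,
      mean_events_per_line = 192 / 14,
      category_probs = c(SBS = 0.5521, del1 = 0.0209, ins1 = 0.0261,
                         del_ge2 = 0.3490, ins_ge2 = 0.0206,
                         complex = 0.0313),
      sbs_class_probs = c(`A/T>G/C` = 0.24, `G/C>A/T` = 0.26,
                          `A/T>T/A` = 0.20, `A/T>C/G` = 0.10,
                          `G/C>T/A` = 0.12, `G/C>C/G` = 0.08),
      indel_ge2_bin_probs = c(`2-10` = 0.45, `11-30` = 0.45, `>30` = 0.10),
      indel_max_len = NA,
      mh_class_probs = c(homopoly = 0.0760,
                         polynucleotide_repeat = 0.6762,
                         independent = 0.2478))
  )
}

#' Generate a synthetic genome with seeded repeats and gene models
#'
#' A single-contig random genome at the requested GC content, overwritten
#' with homopolymer runs (3-12 bp) and perfect tandem repeats (unit 2-6 bp,
#' 2-5 copies) at the stated densities (features per bp), plus
#' non-overlapping gene models with UTR/exon/intron/CDS structure.
#' Byte-identical output for a fixed seed.
#'
#' @param length Genome length in bp (>= 10 kb when genes are requested).
#' @param gc GC fraction (default 0.36, Arabidopsis-like).
#' @param homopolymer_density Seeded homopolymer runs per bp (default
#'   1/1000).
#' @param tandem_repeat_density Seeded tandem repeats per bp (default
#'   1/1000).
#' @param n_genes Number of gene models (default 20).
#' @param seed Integer seed.
#' @return `list(genome, models, repeats)`; `repeats` is a data.frame of
#'   the seeded features (`type`, `start`, `end`, `unit`, `copies`).
#' @export
generate_genome <- function(length = 100000L, gc = 0.36,
                            homopolymer_density = 1 / 1000,
                            tandem_repeat_density = 1 / 1000,
                            n_genes = 20L, seed = 1L) {
  if (n_genes > 0 && length < 10000L) {
    stop("genome must be >= 10 kb to place genes")
  }
  set.seed(seed)
  length <- as.integer(length)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(p), length, replace = TRUE, prob = p)

  occupied <- rep(FALSE, length)
  feats <- list()
  place_feature <- function(flen) {
    # uniform start with rejection against previously seeded features
    for (try in 1:200) {
      s <- sample.int(length - flen - 2L, 1L) + 1L
      if (!any(occupied[s:(s + flen + 1L)])) return(s)
    }
    stop("could not place a seeded feature; lower the repeat densities")
  }

  n_h <- round(length * homopolymer_density)
  for (i in seq_len(n_h)) {
    run <- sample(3:12, 1L)
    s <- place_feature(run)
    base <- sample(c("A", "C", "G", "T"), 1L)
    chars[s:(s + run - 1L)] <- base
    # ensure the run is bounded so its length is exactly `run`
    others <- setdiff(c("A", "C", "G", "T"), base)
    chars[s - 1L] <- sample(others, 1L)
    chars[s + run] <- sample(others, 1L)
    occupied[(s - 1L):(s + run)] <- TRUE
    feats[[length(feats) + 1L]] <- data.frame(
      type = "homopolymer", start = s, end = s + run - 1L, unit = base,
      copies = run, stringsAsFactors = FALSE)
  }

  n_t <- round(length * tandem_repeat_density)
  for (i in seq_len(n_t)) {
    ulen <- sample(2:6, 1L)
    copies <- sample(2:5, 1L)
    unit <- sample(c("A", "C", "G", "T"), ulen, replace = TRUE)
    while (length(unique(unit)) == 1L) {
      unit <- sample(c("A", "C", "G", "T"), ulen, replace = TRUE)
    }
    flen <- ulen * copies
    s <- place_feature(flen)
    chars[s:(s + flen - 1L)] <- rep(unit, copies)
    # break the array cleanly at both ends
    chars[s - 1L] <- setdiff(c("A", "C", "G", "T"), unit[ulen])[1L]
    chars[s + flen] <- setdiff(c("A", "C", "G", "T"), unit[1L])[1L]
    occupied[(s - 1L):(s + flen)] <- TRUE
    feats[[length(feats) + 1L]] <- data.frame(
      type = "tandem_repeat", start = s, end = s + flen - 1L,
      unit = paste(unit, collapse = ""), copies = copies,
      stringsAsFactors = FALSE)
  }

  genome <- stats::setNames(paste(chars, collapse = ""), "chr1")
  models <- place_gene_models(length, n_genes)
  repeats <- if (length(feats)) do.call(rbind, feats) else
    data.frame(type = character(0), start = integer(0), end = integer(0),
               unit = character(0), copies = integer(0),
               stringsAsFactors = FALSE)
  repeats <- repeats[order(repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL
  list(genome = genome, models = models, repeats = repeats)
}

# non-overlapping gene models with UTR/exon/intron/CDS structure on "chr1"
place_gene_models <- function(glen, n_genes) {
  if (n_genes == 0L) return(empty_gene_models())
  rows <- list()
  cursor <- 2000L
  for (i in seq_len(n_genes)) {
    n_ex <- sample(2:4, 1L)
    ex_len <- sample(150:500, n_ex, replace = TRUE)
    in_len <- sample(80:300, n_ex - 1L, replace = TRUE)
    gene_len <- sum(ex_len) + sum(in_len)
    gap <- sample(500:1500, 1L)
    start <- cursor + gap
    end <- start + gene_len - 1L
    if (end > glen - 2000L) break
    cursor <- end
    strand <- sample(c("+", "-"), 1L)
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    s <- start
    for (j in seq_len(n_ex)) {
      ex_start[j] <- s
      ex_end[j] <- s + ex_len[j] - 1L
      s <- ex_end[j] + if (j < n_ex) in_len[j] else 0L
      if (j < n_ex) s <- s + 1L
    }
    # mRNA coordinates: UTRs at the transcript ends, CDS in between with
    # length trimmed to a codon multiple
    mlen <- sum(ex_len)
    u5 <- sample(60:150, 1L)
    u3 <- sample(60:150, 1L)
    cds_len <- mlen - u5 - u3
    cds_len <- cds_len - (cds_len %% 3L)
    u3 <- mlen - u5 - cds_len
    # map transcript interval [u5+1, u5+cds_len] to genomic CDS intervals
    tx_pos <- if (strand == "+") {
      unlist(lapply(seq_len(n_ex), function(j) seq(ex_start[j], ex_end[j])))
    } else {
      unlist(lapply(rev(seq_len(n_ex)),
                    function(j) rev(seq(ex_start[j], ex_end[j]))))
    }
    cds_g <- sort(tx_pos[(u5 + 1L):(u5 + cds_len)])
    brk <- which(diff(cds_g) > 1L)
    cs <- c(cds_g[1L], cds_g[brk + 1L])
    ce <- c(cds_g[brk], cds_g[length(cds_g)])
    if (strand == "-") { ord <- order(cs, decreasing = TRUE) } else {
      ord <- order(cs)
    }
    cdsdf <- data.frame(start = cs[ord], end = ce[ord], phase = 0L)
    # phases follow from cumulative CDS length in transcription order
    if (nrow(cdsdf) > 1L) {
      lens <- cdsdf$end - cdsdf$start + 1L
      cum <- cumsum(c(0L, lens[-length(lens)]))
      cdsdf$phase <- (3L - (cum %% 3L)) %% 3L
    }
    exdf <- data.frame(start = ex_start, end = ex_end)
    if (strand == "-") exdf <- exdf[order(exdf$start, decreasing = TRUE), ]
    rows[[length(rows) + 1L]] <- list(
      gene_id = sprintf("gene%03d", i), contig = "chr1", strand = strand,
      start = start, end = end, tss = if (strand == "-") end else start,
      exons = exdf, cds = cdsdf)
  }
  if (!length(rows)) return(empty_gene_models())
  data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    contig = vapply(rows, `[[`, character(1), "contig"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    tss = vapply(rows, `[[`, numeric(1), "tss"),
    exons = I(lapply(rows, `[[`, "exons")),
    cds = I(lapply(rows, `[[`, "cds")),
    stringsAsFactors = FALSE)
}

#' Generate per-line mutation calls from a genotype profile
#'
#' Per line, the event count is Poisson(`mean_events_per_line`); categories,
#' SBS classes and InDel lengths are drawn from the profile. InDels
#' targeted at the `homopoly` / `polynucleotide_repeat` signature classes
#' are placed inside seeded runs / tandem arrays (and verified against the
#' signature classifier); `independent` InDels are placed in unique context.
#' Complex events are emitted as two SBS calls within 10 bp. Placement
#' mixes TSS-proximal exponential decay with uniform positions. The target
#' line's read fraction is Beta(20, 20) (heterozygous M2), other lines 0;
#' optional shared background variants (read fraction about 0.5 in two or
#' more lines) and low-support calls are appended for filter testing.
#'
#' @param sim Output of [generate_genome()] (`genome`, `models`,
#'   `repeats`), or a list with those elements.
#' @param profile A [genotype_profile()].
#' @param seed Integer seed.
#' @param n_background Shared background variants appended (default 5).
#' @param n_low_af Low-support calls appended (default 5).
#' @return `list(calls, truth, meta)`: the call table (with `af_<line>`
#'   columns), one truth record per generated event, and line metadata.
#' @export
generate_mutations <- function(sim, profile, seed = 1L, n_background = 5L,
                               n_low_af = 5L) {
  set.seed(seed)
  genome <- sim$genome
  models <- sim$models
  repeats <- sim$repeats
  contig <- names(genome)[1L]
  seq <- genome[[contig]]
  L <- nchar(seq)
  lines <- sprintf("%s_L%02d", profile$name, seq_len(profile$n_lines))
  meta <- data.frame(line_id = lines, genotype = profile$name,
                     dose = profile$dose, generation = "M2",
                     stringsAsFactors = FALSE)

  hruns <- repeats[repeats$type == "homopolymer", , drop = FALSE]
  arrays <- repeats[repeats$type == "tandem_repeat", , drop = FALSE]
  mh_cfg <- mh_config()

  draw_pos <- function() {
    if (nrow(models) > 0 && stats::runif(1) < profile$tss_bias$weight) {
      g <- models[sample.int(nrow(models), 1L), ]
      d <- round(stats::rexp(1, 1 / profile$tss_bias$scale)) *
        sample(c(-1L, 1L), 1L)
      p <- if (g$strand == "-") g$tss - d else g$tss + d
      min(max(p, 50L), L - 60L)
    } else {
      sample.int(L - 110L, 1L) + 50L
    }
  }

  calls <- list()
  truth <- list()
  base_at <- function(p) substr(seq, p, p)

  for (line in lines) {
    n_ev <- stats::rpois(1L, profile$mean_events_per_line)
    used_s <- integer(0)
    used_e <- integer(0)
    reserve <- function(p, width = 1L) {
      # keep reference footprints of one line's events > 15 bp apart so
      # they never chain into accidental complex clusters (window 10)
      s <- p - 15L
      e <- p + width + 15L
      if (any(used_s <= e & used_e >= s)) return(FALSE)
      used_s <<- c(used_s, p)
      used_e <<- c(used_e, p + width)
      TRUE
    }
    for (e in seq_len(n_ev)) {
      cat_ <- sample(names(profile$category_probs), 1L,
                     prob = profile$category_probs)
      af <- stats::rbeta(1, 20, 20)
      if (cat_ == "SBS") {
        cls <- sample(SBS_CLASSES, 1L, prob = profile$sbs_class_probs)
        pair <- if (startsWith(cls, "A/T")) c("A", "T") else c("G", "C")
        for (try in 1:100) {
          p <- draw_pos()
          if (base_at(p) %in% pair && reserve(p)) break
          p <- NA_integer_
        }
        if (is.na(p)) next
        ref <- base_at(p)
        alt <- sbs_alt_for_class(ref, cls)
        calls[[length(calls) + 1L]] <- list(contig = contig, pos = p,
                                            ref = ref, alt = alt,
                                            line_id = line, af = af)
        truth[[length(truth) + 1L]] <- list(
          line_id = line, category = "SBS", sbs_class = cls,
          mh_class = NA_character_, indel_len = 0L, pos = p)
      } else if (cat_ == "complex") {
        gap <- sample(2:8, 1L)
        for (try in 1:100) {
          p <- draw_pos()
          if (p + gap <= L - 50L && base_at(p) != "N" &&
              base_at(p + gap) != "N" && reserve(p, gap + 1L)) break
          p <- NA_integer_
        }
        if (is.na(p)) next
        for (pp in c(p, p + gap)) {
          ref <- base_at(pp)
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
          calls[[length(calls) + 1L]] <- list(contig = contig, pos = pp,
                                              ref = ref, alt = alt,
                                              line_id = line, af = af)
        }
        truth[[length(truth) + 1L]] <- list(
          line_id = line, category = "complex", sbs_class = NA_character_,
          mh_class = NA_character_, indel_len = NA_integer_, pos = p)
      } else {
        is_del <- cat_ %in% c("del1", "del_ge2")
        len <- if (cat_ %in% c("del1", "ins1")) 1L else draw_ge2_len(profile)
        mh_target <- sample(names(profile$mh_class_probs), 1L,
                            prob = profile$mh_class_probs)
        placed <- place_indel(mh_target, is_del, len, seq, contig, hruns,
                              arrays, draw_pos, reserve, genome, mh_cfg)
        if (is.null(placed)) next
        calls[[length(calls) + 1L]] <- c(placed$call,
                                         list(line_id = line, af = af))
        truth[[length(truth) + 1L]] <- list(
          line_id = line, category = recategorize_indel(placed$len, is_del),
          sbs_class = NA_character_, mh_class = placed$mh_class,
          indel_len = as.integer(if (is_del) -placed$len else placed$len),
          pos = placed$call$pos)
      }
    }
  }

  af_m <- matrix(0, length(calls), length(lines),
                 dimnames = list(NULL, lines))
  for (i in seq_along(calls)) af_m[i, calls[[i]]$line_id] <- calls[[i]]$af

  df <- variant_calls(
    vapply(calls, `[[`, character(1), "contig"),
    vapply(calls, `[[`, numeric(1), "pos"),
    vapply(calls, `[[`, character(1), "ref"),
    vapply(calls, `[[`, character(1), "alt"),
    vapply(calls, `[[`, character(1), "line_id"), af_m)

  # shared background variants (pre-existing heterozygous sites carried by
  # two or more lines) and low-support noise calls, for filter testing
  extra <- synth_background(contig, seq, L, lines, n_background, n_low_af)
  if (!is.null(extra)) df <- rbind(df, extra)

  truth_df <- data.frame(
    line_id = vapply(truth, `[[`, character(1), "line_id"),
    category = vapply(truth, `[[`, character(1), "category"),
    sbs_class = vapply(truth, `[[`, character(1), "sbs_class"),
    mh_class = vapply(truth, `[[`, character(1), "mh_class"),
    indel_len = vapply(truth, `[[`, integer(1), "indel_len"),
    pos = vapply(truth, `[[`, numeric(1), "pos"),
    stringsAsFactors = FALSE)

  list(calls = df, truth = truth_df, meta = meta)
}

# alt base realizing an SBS class at a concrete reference base
sbs_alt_for_class <- function(ref, cls) {
  to <- sub(".*>", "", cls)               # e.g. "G/C" from "A/T>G/C"
  first <- substr(to, 1L, 1L)
  second <- substr(to, 3L, 3L)
  # the collapse maps A,G to the printed left base and T,C to its complement
  if (ref %in% c("A", "G")) first else second
}

draw_ge2_len <- function(profile) {
  bin <- sample(names(profile$indel_ge2_bin_probs), 1L,
                prob = profile$indel_ge2_bin_probs)
  len <- switch(bin,
                "2-10" = sample(2:10, 1L),
                "11-30" = sample(11:30, 1L),
                ">30" = sample(31:60, 1L))
  if (!is.na(profile$indel_max_len)) len <- min(len, profile$indel_max_len)
  len
}

recategorize_indel <- function(len, is_del) {
  if (len == 1L) { if (is_del) "del1" else "ins1" }
  else { if (is_del) "del_ge2" else "ins_ge2" }
}

# place one InDel so its microhomology signature matches the target class;
# returns list(call = list(contig,pos,ref,alt), len, mh_class) or NULL
place_indel <- function(mh_target, is_del, len, seq, contig, hruns, arrays,
                        draw_pos, reserve, genome, mh_cfg) {
  L <- nchar(seq)
  mk_del <- function(s, dlen) {
    if (s < 2L || s + dlen - 1L > L) return(NULL)
    list(contig = contig, pos = s - 1L,
         ref = substr(seq, s - 1L, s + dlen - 1L),
         alt = substr(seq, s - 1L, s - 1L))
  }
  mk_ins <- function(p, ins) {
    if (p < 1L || p > L) return(NULL)
    list(contig = contig, pos = p, ref = substr(seq, p, p),
         alt = paste0(substr(seq, p, p), ins))
  }
  check <- function(call, want) {
    # classify the normalized representation, exactly as the pipeline will
    norm <- normalize_one(call$contig, call$pos, call$ref, call$alt,
                          genome)
    if (nrow(norm) != 1L) return(FALSE)
    sig <- classify_dependency(list(contig = call$contig, pos = norm$pos,
                                    ref = norm$ref, alt = norm$alt),
                               genome, mh_cfg)
    identical(sig$dependency_class, want)
  }
  for (try in 1:60) {
    cand <- NULL
    used_len <- len
    if (mh_target == "homopoly") {
      # runs are at most 12 bp, so longer draws snap to the longest run
      eff_len <- if (is_del) min(len, max(hruns$copies, 0L)) else len
      if (eff_len < 1L) return(NULL)
      ok <- hruns[hruns$copies >= max(3L, if (is_del) eff_len else 3L), ,
                  drop = FALSE]
      if (nrow(ok) == 0L) return(NULL)
      r <- ok[sample.int(nrow(ok), 1L), ]
      used_len <- eff_len
      if (is_del) {
        cand <- mk_del(r$start, eff_len)
      } else {
        cand <- mk_ins(r$start,
                       strrep(substr(seq, r$start, r$start), eff_len))
      }
    } else if (mh_target == "polynucleotide_repeat") {
      if (nrow(arrays) == 0L) return(NULL)
      ulen <- nchar(arrays$unit)
      span <- arrays$end - arrays$start + 1L
      ok <- arrays[span >= len + ulen, , drop = FALSE]
      if (nrow(ok) == 0L) ok <- arrays   # snap length into the span below
      r <- ok[sample.int(nrow(ok), 1L), ]
      rulen <- nchar(r$unit)
      rspan <- r$end - r$start + 1L
      if (is_del) {
        dlen <- max(1L, min(len, rspan - rulen))
        used_len <- dlen
        cand <- mk_del(r$start, dlen)
      } else if (len == 1L) {
        # 1-bp insertion inside the array (junction covered by the array)
        p <- r$start + sample.int(rspan - 2L, 1L)
        cand <- mk_ins(p, substr(seq, p + 1L, p + 1L))
      } else {
        # insert whole unit copies at a unit boundary
        d <- max(1L, len %/% rulen)
        used_len <- d * rulen
        cand <- mk_ins(r$start + rulen - 1L, strrep(r$unit, d))
      }
    } else {                              # independent
      p <- draw_pos()
      if (is_del) {
        cand <- mk_del(p, len)
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        cand <- mk_ins(p, ins)
      }
    }
    if (is.null(cand)) next
    if (!check(cand, mh_target)) next
    if (!reserve(cand$pos, nchar(cand$ref) + 1L)) next
    return(list(call = cand, len = used_len, mh_class = mh_target))
  }
  NULL
}

# shared and low-support background calls appended to a simulated call set
synth_background <- function(contig, seq, L, lines, n_background,
                             n_low_af) {
  rows <- list()
  base_at <- function(p) substr(seq, p, p)
  for (i in seq_len(n_background)) {
    p <- sample.int(L - 100L, 1L) + 50L
    ref <- base_at(p)
    if (ref == "N") next
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    carriers <- sample(lines, min(length(lines),
                                  sample(2:max(2L, min(4L,
                                                       length(lines))),
                                         1L)))
    af <- stats::setNames(rep(0, length(lines)), lines)
    af[carriers] <- round(stats::rbeta(length(carriers), 20, 20), 3)
    for (cl in carriers) {
      rows[[length(rows) + 1L]] <- list(contig = contig, pos = p,
                                        ref = ref, alt = alt,
                                        line_id = cl, af = af)
    }
  }
  for (i in seq_len(n_low_af)) {
    p <- sample.int(L - 100L, 1L) + 50L
    ref <- base_at(p)
    if (ref == "N") next
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    target <- sample(lines, 1L)
    af <- stats::setNames(rep(0, length(lines)), lines)
    af[target] <- round(stats::runif(1, 0.02, 0.2), 3)
    rows[[length(rows) + 1L]] <- list(contig = contig, pos = p, ref = ref,
                                      alt = alt, line_id = target,
                                      af = af)
  }
  if (!length(rows)) return(NULL)
  m <- do.call(rbind, lapply(rows, `[[`, "af"))
  colnames(m) <- lines
  variant_calls(vapply(rows, `[[`, character(1), "contig"),
                vapply(rows, `[[`, numeric(1), "pos"),
                vapply(rows, `[[`, character(1), "ref"),
                vapply(rows, `[[`, character(1), "alt"),
                vapply(rows, `[[`, character(1), "line_id"), m)
}
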