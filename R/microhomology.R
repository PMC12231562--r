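# Junction microhomology and flanking-sequence signature classification.
#
# For each InDel the allele sequence A is the deleted bases (deletion) or
# the inserted bases (insertion). The junction microhomology length m is the
# longest k <= min(|A|, cap) such that the k-prefix of A equals the k
# reference bases immediately 3' of the event, or the k-suffix of A equals
# the k bases immediately 5' of it. Alt-EJ junctions typically use 2-20 bp
# of microhomology, which motivates the 20 bp cap and scan window.
#
# Each InDel is then classified into one of three mutually exclusive
# flanking-signature classes:
#   homopoly               - mononucleotide allele inside a homopolymer run
#   polynucleotide_repeat  - junction covered by a perfect tandem repeat of
#                            unit length >= 2, or a >= 2 bp allele with
#                            >= 1 bp of junction microhomology
#   independent            - neither feature present

#' Microhomology scan configuration
#'
#' @param flank_window Scan window on either side of the junction, bp
#'   (default 20).
#' @param mh_cap Maximum microhomology length reported (default 20).
#' @param homopoly_min_run Minimum reference homopolymer run length for the
#'   `homopoly` class (default 3).
#' @param repeat_unit_min,repeat_unit_max Tandem-repeat unit lengths
#'   considered (defaults 2 and 10).
#' @param repeat_min_copies Minimum perfect copies of the unit (default 2).
#' @return A validated `mh_config` list.
#' @export
mh_config <- function(flank_window = 20L, mh_cap = 20L,
                      homopoly_min_run = 3L, repeat_unit_min = 2L,
                      repeat_unit_max = 10L, repeat_min_copies = 2L) {
  stopifnot(flank_window > 0, mh_cap > 0, homopoly_min_run > 0,
            repeat_unit_min >= 2, repeat_unit_max >= repeat_unit_min,
            repeat_min_copies >= 2)
  structure(list(flank_window = as.integer(flank_window),
                 mh_cap = as.integer(mh_cap),
                 homopoly_min_run = as.integer(homopoly_min_run),
                 repeat_unit_min = as.integer(repeat_unit_min),
                 repeat_unit_max = as.integer(repeat_unit_max),
                 repeat_min_copies = as.integer(repeat_min_copies)),
            class = "mh_config")
}

# decompose a normalized, anchored InDel event/call into its allele
# geometry: type ("del"/"ins"), allele string A, and the junction interval
# on the reference (deleted bases for deletions; the two bases flanking the
# insertion point for insertions).
indel_geometry <- function(contig, pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) stop("not an InDel: ", contig, ":", pos, " ", ref, ">", alt)
  if (nr > na) {
    list(type = "del", allele = substr(ref, na + 1L, nr),
         jstart = pos + na, jend = pos + nr - 1L, ins_point = NA_integer_)
  } else {
    list(type = "ins", allele = substr(alt, nr + 1L, na),
         jstart = pos + nr - 1L, jend = pos + nr, ins_point = pos + nr - 1L)
  }
}

# length of the common prefix of two strings, stopping at N
common_prefix_len <- function(x, y, cap = Inf) {
  n <- min(nchar(x), nchar(y), cap)
  if (n == 0) return(0L)
  xb <- strsplit(substr(x, 1L, n), "")[[1]]
  yb <- strsplit(substr(y, 1L, n), "")[[1]]
  mismatch <- which(xb != yb | xb == "N" | yb == "N")
  if (length(mismatch) == 0L) as.integer(n) else mismatch[1L] - 1L
}

reverse_chars <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

#' Junction microhomology of an InDel
#'
#' @param event One-row event data.frame (or anything with `contig`, `start`
#'   or `pos`, `ref`, `alt`) describing a normalized InDel.
#' @param genome Named character vector of contig sequences.
#' @param cfg An [mh_config()].
#' @return `list(mh_len, mh_side)` with side one of `left`, `right`, `both`,
#'   `none`.
#' @export
junction_microhomology <- function(event, genome, cfg = mh_config()) {
  pos <- if (!is.null(event$pos)) event$pos else event$start
  geo <- indel_geometry(event$contig, pos, event$ref, event$alt)
  A <- geo$allele
  cap <- min(nchar(A), cfg$mh_cap)
  if (geo$type == "del") {
    right_flank <- genome_slice(genome, event$contig, geo$jend + 1L,
                                geo$jend + cap)
    left_flank <- genome_slice(genome, event$contig, geo$jstart - cap,
                               geo$jstart - 1L)
  } else {
    p <- geo$ins_point
    right_flank <- genome_slice(genome, event$contig, p + 1L, p + cap)
    left_flank <- genome_slice(genome, event$contig, p - cap + 1L, p)
  }
  k_right <- common_prefix_len(A, right_flank, cap)
  k_left <- common_prefix_len(reverse_chars(A), reverse_chars(left_flank),
                              cap)
  m <- max(k_right, k_left)
  side <- if (m == 0L) "none"
    else if (k_right == m && k_left == m) "both"
    else if (k_right == m) "right" else "left"
  list(mh_len = as.integer(m), mh_side = side)
}

#' Longest homopolymer run at an InDel junction
#'
#' The length of the longest single-base reference run overlapping the
#' junction interval: the deleted bases for deletions, the two bases
#' adjacent to the insertion point for insertions.
#'
#' @inheritParams junction_microhomology
#' @return Integer run length `H`.
#' @export
homopolymer_run <- function(event, genome, cfg = mh_config()) {
  pos <- if (!is.null(event$pos)) event$pos else event$start
  geo <- indel_geometry(event$contig, pos, event$ref, event$alt)
  L <- nchar(genome[[event$contig]])
  a <- max(1L, geo$jstart); b <- min(L, geo$jend)
  # runs overlapping [a,b] cannot extend beyond this padded region in any
  # data this pipeline sees (pad >> max InDel + max run length)
  pad <- 500L
  rs <- max(1L, a - pad); re <- min(L, b + pad)
  region <- substr(genome[[event$contig]], rs, re)
  r <- rle(strsplit(region, "")[[1]])
  ends <- cumsum(r$lengths) + rs - 1L
  starts <- ends - r$lengths + 1L
  hit <- starts <= b & ends >= a & r$values != "N"
  if (!any(hit)) return(0L)
  as.integer(max(r$lengths[hit]))
}

#' Tandem-repeat context of an InDel junction
#'
#' Searches `+-flank_window` of reference around the junction for a perfect
#' tandem array (unit length `repeat_unit_min..repeat_unit_max`, at least
#' `repeat_min_copies` copies, unit not a mononucleotide) covering the
#' junction interval — the deleted bases for deletions, the two bases
#' flanking the insertion point for insertions (mirroring
#' [homopolymer_run()]). The shortest qualifying unit is returned. Note a
#' tandem-duplication insertion next to a single-copy unit is still scored
#' repeat-dependent downstream, through its junction microhomology.
#'
#' @inheritParams junction_microhomology
#' @return The repeat unit string, or `NA` if none qualifies.
#' @export
tandem_repeat_context <- function(event, genome, cfg = mh_config()) {
  pos <- if (!is.null(event$pos)) event$pos else event$start
  geo <- indel_geometry(event$contig, pos, event$ref, event$alt)
  fw <- cfg$flank_window
  rs <- max(1L, geo$jstart - fw)
  region <- genome_slice(genome, event$contig, rs, geo$jend + fw)
  ja <- geo$jstart - rs + 1L
  jb <- geo$jend - rs + 1L
  find_covering_unit(region, ja, jb, cfg)
}

# scan a region string for a perfect tandem array of period u (unit not
# mononucleotide, >= min copies) whose interval covers [ja, jb]; units are
# tried in increasing length so the shortest wins
find_covering_unit <- function(region, ja, jb, cfg) {
  chars <- strsplit(region, "")[[1]]
  n <- length(chars)
  for (u in seq(cfg$repeat_unit_min, cfg$repeat_unit_max)) {
    if (n < u * cfg$repeat_min_copies) break
    m <- chars[seq_len(n - u)] == chars[seq_len(n - u) + u] &
      chars[seq_len(n - u)] != "N"
    r <- rle(m)
    pos0 <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      i0 <- pos0[j]
      alen <- r$lengths[j] + u          # array spans [i0, i0 + alen - 1]
      if (alen < u * cfg$repeat_min_copies) next
      i1 <- i0 + alen - 1L
      if (i0 <= ja && i1 >= jb) {
        unit <- paste(chars[i0:(i0 + u - 1L)], collapse = "")
        if (length(unique(strsplit(unit, "")[[1]])) > 1L) return(unit)
      }
    }
  }
  NA_character_
}

#' Classify the flanking-sequence signature of an InDel
#'
#' Applies, in priority order: `homopoly` when the allele is a
#' mononucleotide and the junction homopolymer run is at least
#' `homopoly_min_run`; else `polynucleotide_repeat` when a covering tandem
#' repeat exists or a `>= 2` bp allele shows `>= 1` bp of junction
#' microhomology; else `independent`. Junction windows containing `N` are
#' classified `independent` with `ambiguous_context = TRUE`.
#'
#' @inheritParams junction_microhomology
#' @return `list(mh_len, mh_side, homopolymer_run, repeat_unit,
#'   dependency_class, ambiguous_context)`.
#' @export
classify_dependency <- function(event, genome, cfg = mh_config()) {
  pos <- if (!is.null(event$pos)) event$pos else event$start
  geo <- indel_geometry(event$contig, pos, event$ref, event$alt)
  mh <- junction_microhomology(event, genome, cfg)
  H <- homopolymer_run(event, genome, cfg)
  ru <- tandem_repeat_context(event, genome, cfg)
  window <- genome_slice(genome, event$contig,
                         geo$jstart - cfg$flank_window,
                         geo$jend + cfg$flank_window)
  ambiguous <- grepl("N", window, fixed = TRUE) ||
    grepl("N", geo$allele, fixed = TRUE)
  mono <- length(unique(strsplit(geo$allele, "")[[1]])) == 1L
  cls <- if (ambiguous) {
    "independent"
  } else if (mono && H >= cfg$homopoly_min_run) {
    "homopoly"
  } else if (!is.na(ru) ||
             (nchar(geo$allele) >= 2L && mh$mh_len >= 1L)) {
    "polynucleotide_repeat"
  } else {
    "independent"
  }
  list(mh_len = mh$mh_len, mh_side = mh$mh_side, homopolymer_run = H,
       repeat_unit = ru, dependency_class = cls,
       ambiguous_context = ambiguous)
}

#' Microhomology signatures for all InDel events
#'
#' Runs [classify_dependency()] on every non-complex InDel event and returns
#' one signature row per event.
#'
#' @param events Event data.frame from [classify_events()].
#' @param genome Named character vector of contig sequences.
#' @param cfg An [mh_config()].
#' @return Data.frame with the event keys plus `mh_len`, `mh_side`,
#'   `homopolymer_run`, `repeat_unit`, `dependency_class`,
#'   `ambiguous_context`.
#' @export
classify_microhomology <- function(events, genome, cfg = mh_config()) {
  idx <- which(events$category %in% c("del1", "ins1", "del_ge2", "ins_ge2"))
  base <- events[idx, c("line_id", "contig", "start", "end", "category",
                        "indel_len", "length_bin"), drop = FALSE]
  sig <- lapply(idx, function(i) {
    ev <- list(contig = events$contig[i], pos = events$start[i],
               ref = events$ref[i], alt = events$alt[i])
    classify_dependency(ev, genome, cfg)
  })
  base$mh_len <- vapply(sig, `[[`, integer(1), "mh_len")
  base$mh_side <- vapply(sig, `[[`, character(1), "mh_side")
  base$homopolymer_run <- vapply(sig, `[[`, integer(1), "homopolymer_run")
  base$repeat_unit <- vapply(sig, `[[`, character(1), "repeat_unit")
  base$dependency_class <- vapply(sig, `[[`, character(1),
                                  "dependency_class")
  base$ambiguous_context <- vapply(sig, `[[`, logical(1),
                                   "ambiguous_context")
  rownames(base) <- NULL
  base
}
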