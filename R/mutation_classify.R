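# Seven-category mutation classification and complex-event clustering.
#
# Categories: SBS, del1 (-1 bp), ins1 (+1 bp), del_ge2 (deletions >= 2 bp),
# ins_ge2 (insertions >= 2 bp), complex (>= 2 mutations within 10 bp treated
# as one event), and SV (assigned only by the SV module, never here).

MUTATION_CATEGORIES <- c("SBS", "del1", "ins1", "del_ge2", "ins_ge2",
                         "complex", "SV")

SBS_CLASSES <- c("A/T>G/C", "G/C>A/T", "A/T>T/A", "A/T>C/G", "G/C>T/A",
                 "G/C>C/G")

INDEL_LENGTH_BINS <- c("1", "2-10", "11-30", ">30")

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Strand-collapsed SBS class
#'
#' Substitutions are collapsed onto the A/T- or G/C-reference strand, giving
#' six classes; e.g. both `G>A` and `C>T` are `G/C>A/T`.
#'
#' @param ref_base,alt_base Single reference/alternate bases (vectorized).
#' @return Character vector of classes among
#'   `A/T>G/C, G/C>A/T, A/T>T/A, A/T>C/G, G/C>T/A, G/C>C/G`.
#' @seealso [is_transition()]
#' @export
classify_sbs <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  ok <- ref_base %in% c("A", "C", "G", "T") &
    alt_base %in% c("A", "C", "G", "T") & ref_base != alt_base
  if (!all(ok)) {
    stop("invalid SBS: ref/alt must be distinct single bases in ACGT")
  }
  flip <- ref_base %in% c("C", "T")
  r <- ifelse(flip, DNA_COMPLEMENT[ref_base], ref_base)
  a <- ifelse(flip, DNA_COMPLEMENT[alt_base], alt_base)
  # after collapsing, the reference base is A or G; enumerate the six cases
  out <- character(length(r))
  out[r == "A" & a == "G"] <- "A/T>G/C"
  out[r == "A" & a == "T"] <- "A/T>T/A"
  out[r == "A" & a == "C"] <- "A/T>C/G"
  out[r == "G" & a == "A"] <- "G/C>A/T"
  out[r == "G" & a == "T"] <- "G/C>T/A"
  out[r == "G" & a == "C"] <- "G/C>C/G"
  out
}

#' Is an SBS class a transition?
#'
#' @param sbs_class Class label from [classify_sbs()].
#' @return Logical; `TRUE` for `A/T>G/C` and `G/C>A/T`.
#' @export
is_transition <- function(sbs_class) sbs_class %in% c("A/T>G/C", "G/C>A/T")

# signed indel length of a normalized call: + insertion, - deletion, 0 SBS
call_indel_len <- function(ref, alt) nchar(alt) - nchar(ref)

# reference footprint of a normalized call (1-based inclusive)
call_footprint <- function(pos, ref) {
  data.frame(start = pos, end = pos + nchar(ref) - 1L)
}

#' InDel length bin
#'
#' Bins used for the InDel length spectrum: 1, 2-10, 11-30, >30 bp.
#'
#' @param len Signed or absolute InDel lengths.
#' @return Character vector of bin labels.
#' @export
indel_length_bin <- function(len) {
  a <- abs(len)
  out <- rep(NA_character_, length(a))
  out[a == 1] <- "1"
  out[a >= 2 & a <= 10] <- "2-10"
  out[a >= 11 & a <= 30] <- "11-30"
  out[a > 30] <- ">30"
  out
}

# assign cluster ids per (line, contig): successive calls chain into one
# cluster when gap = start(next) - end(previous footprint) <= window
cluster_ids <- function(calls, window) {
  n <- nrow(calls)
  ids <- integer(n)
  ord <- order(calls$line_id, calls$contig, calls$pos)
  cur <- 0L
  prev_line <- prev_contig <- ""
  prev_end <- -Inf
  for (i in ord) {
    fp <- call_footprint(calls$pos[i], calls$ref[i])
    new_cluster <- calls$line_id[i] != prev_line ||
      calls$contig[i] != prev_contig ||
      (fp$start - prev_end) > window
    if (new_cluster) cur <- cur + 1L
    ids[i] <- cur
    prev_line <- calls$line_id[i]
    prev_contig <- calls$contig[i]
    prev_end <- if (new_cluster) fp$end else max(prev_end, fp$end)
  }
  ids
}

#' Classify retained calls into mutation events
#'
#' Calls from one line on one contig are chained into a single `complex`
#' event when the gap between the end of the previous call's reference
#' footprint and the start of the next is at most `window` bp (transitive
#' chaining). Singleton clusters are classified as SBS / del1 / ins1 /
#' del_ge2 / ins_ge2 from their normalized alleles.
#'
#' @param calls Normalized variant-call data.frame (see
#'   [normalize_variants()]).
#' @param window Clustering gap in bp (default 10).
#' @return A data.frame of events with columns `line_id`, `contig`, `start`,
#'   `end`, `category`, `sbs_class`, `indel_len`, `length_bin`,
#'   `member_count`, `ref`, `alt` (alleles are `NA` for complex events) and
#'   a list-column `members` holding the constituent calls of complex
#'   events.
#' @export
classify_events <- function(calls, window = 10) {
  if (nrow(calls) == 0L) {
    return(data.frame(line_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      category = character(0), sbs_class = character(0),
                      indel_len = integer(0), length_bin = character(0),
                      member_count = integer(0), ref = character(0),
                      alt = character(0), members = I(list()),
                      stringsAsFactors = FALSE))
  }
  ids <- cluster_ids(calls, window)
  rows <- lapply(split(seq_len(nrow(calls)), ids), function(idx) {
    members <- calls[idx, , drop = FALSE]
    fp <- call_footprint(members$pos, members$ref)
    if (length(idx) == 1L) {
      ref <- members$ref; alt <- members$alt
      il <- call_indel_len(ref, alt)
      if (nchar(ref) == 1L && nchar(alt) == 1L) {
        cat_ <- "SBS"; sbs <- classify_sbs(ref, alt); bin <- NA_character_
        il <- 0L
      } else {
        cat_ <- if (il == -1) "del1" else if (il == 1) "ins1"
          else if (il <= -2) "del_ge2" else "ins_ge2"
        sbs <- NA_character_
        bin <- indel_length_bin(il)
      }
      list(line_id = members$line_id, contig = members$contig,
           start = min(fp$start), end = max(fp$end), category = cat_,
           sbs_class = sbs, indel_len = as.integer(il), length_bin = bin,
           member_count = 1L, ref = ref, alt = alt, members = members)
    } else {
      list(line_id = members$line_id[1], contig = members$contig[1],
           start = min(fp$start), end = max(fp$end), category = "complex",
           sbs_class = NA_character_, indel_len = NA_integer_,
           length_bin = NA_character_, member_count = length(idx),
           ref = NA_character_, alt = NA_character_, members = members)
    }
  })
  out <- data.frame(
    line_id = vapply(rows, `[[`, character(1), "line_id"),
    contig = vapply(rows, `[[`, character(1), "contig"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    category = vapply(rows, `[[`, character(1), "category"),
    sbs_class = vapply(rows, `[[`, character(1), "sbs_class"),
    indel_len = vapply(rows, `[[`, integer(1), "indel_len"),
    length_bin = vapply(rows, `[[`, character(1), "length_bin"),
    member_count = vapply(rows, `[[`, integer(1), "member_count"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    members = I(lapply(rows, `[[`, "members")),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$line_id, out$contig, out$start), , drop = FALSE]
}

#' Cluster calls into complex events
#'
#' Same clustering as [classify_events()]; provided as the named operation
#' for the "two or more mutations within 10 bp count as one event" rule.
#'
#' @inheritParams classify_events
#' @return Event data.frame (see [classify_events()]).
#' @export
cluster_complex <- function(calls, window = 10) {
  classify_events(calls, window = window)
}
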