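# Retention filtering of induced, line-private mutations.
#
# A call is retained when its variant-supporting read fraction is >= 25% in
# the target line, below 5% in every other sequenced line, and the variant
# is not carried by two or more lines (shared/background variants, which
# predate irradiation, are removed).

#' Filter configuration
#'
#' @param af_target_min Minimum variant-supporting read fraction in the
#'   target line (inclusive; default 0.25).
#' @param af_other_max Read-fraction threshold at or above which another
#'   line counts as carrying the variant (exclusive upper bound for
#'   retention; default 0.05).
#' @param shared_line_min Number of carrier lines at which a variant counts
#'   as shared (default 2).
#' @return A validated `filter_config` list.
#' @export
filter_config <- function(af_target_min = 0.25, af_other_max = 0.05,
                          shared_line_min = 2L) {
  stopifnot(af_other_max >= 0, af_other_max < af_target_min,
            af_target_min <= 1, shared_line_min >= 2)
  structure(list(af_target_min = af_target_min,
                 af_other_max = af_other_max,
                 shared_line_min = as.integer(shared_line_min)),
            class = "filter_config")
}

#' Retain line-private, well-supported variants
#'
#' Partitions calls into retained and removed sets. A call owned by target
#' line `t` is retained iff its fraction in `t` is `>= af_target_min`, its
#' fraction is `< af_other_max` in every other line, and fewer than
#' `shared_line_min` lines carry it (fraction `>= af_other_max`). Removed
#' calls are tagged with a reason: `low_af_target`, `shared`, or
#' `present_in_other`.
#'
#' @param calls Variant-call data.frame with `af_<line>` columns.
#' @param lines Character vector of sequenced line ids (or a line-metadata
#'   data.frame with a `line_id` column).
#' @param cfg A [filter_config()].
#' @return `list(retained = <calls>, removed = <calls + reason column>)`.
#' @export
filter_variants <- function(calls, lines, cfg = filter_config()) {
  if (is.data.frame(lines)) lines <- lines$line_id
  lines <- as.character(lines)
  bad <- setdiff(unique(calls$line_id), lines)
  if (length(bad)) {
    stop("call line_id(s) not in the sequenced-line list: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(calls) == 0L) {
    removed <- calls
    removed$reason <- character(0)
    return(list(retained = calls, removed = removed))
  }
  have <- intersect(paste0("af_", lines), names(calls))
  af <- as.matrix(calls[have])
  colnames(af) <- sub("^af_", "", have)
  # lines absent from the table have zero supporting reads
  missing <- setdiff(lines, colnames(af))
  if (length(missing)) {
    af <- cbind(af, matrix(0, nrow(af), length(missing),
                           dimnames = list(NULL, missing)))
  }
  af_target <- af[cbind(seq_len(nrow(calls)),
                        match(calls$line_id, colnames(af)))]
  other <- af
  other[cbind(seq_len(nrow(calls)),
              match(calls$line_id, colnames(af)))] <- 0
  max_other <- apply(other, 1L, max)
  carriers <- rowSums(af >= cfg$af_other_max)

  low_target <- af_target < cfg$af_target_min
  shared <- carriers >= cfg$shared_line_min
  in_other <- max_other >= cfg$af_other_max
  keep <- !low_target & !shared & !in_other

  reason <- rep(NA_character_, nrow(calls))
  reason[in_other] <- "present_in_other"
  reason[shared] <- "shared"
  reason[low_target] <- "low_af_target"

  removed <- calls[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(retained = calls[keep, , drop = FALSE], removed = removed)
}
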