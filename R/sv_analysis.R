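# Structural-variant records: sizes, multi-caller consensus, per-genotype
# summaries. Interval-scale SVs only (DEL/DUP/INV); size = end - start.

SV_TYPES <- c("DEL", "DUP", "INV", "INS", "BND")

#' Construct an SV record table
#'
#' @param line_id,contig,start,end,sv_type Vectors describing one record per
#'   element; `start < end` for interval types.
#' @param callers Character vector (comma-separated caller names per
#'   record), default `"other"`.
#' @param validated Logical vector (manually confirmed, e.g. in IGV),
#'   default `FALSE`.
#' @param genotype Optional genotype label per record.
#' @return Data.frame of SV records with a computed `size` column.
#' @export
sv_records <- function(line_id, contig, start, end, sv_type,
                       callers = "other", validated = FALSE,
                       genotype = NA_character_) {
  sv_type <- toupper(sv_type)
  stopifnot(all(sv_type %in% SV_TYPES))
  df <- data.frame(line_id = as.character(line_id),
                   contig = as.character(contig),
                   start = as.numeric(start), end = as.numeric(end),
                   sv_type = sv_type,
                   callers = as.character(callers),
                   validated = as.logical(validated),
                   genotype = as.character(genotype),
                   stringsAsFactors = FALSE)
  df$size <- vapply(seq_len(nrow(df)), function(i)
    sv_size(df[i, , drop = FALSE]), numeric(1))
  df
}

#' Size of an SV record
#'
#' @param record One-row SV record (interval type).
#' @return `end - start` in bp.
#' @export
sv_size <- function(record) {
  if (record$start >= record$end) {
    stop(sprintf("invalid SV record %s:%s-%s: start must be < end",
                 record$contig, format(record$start, scientific = FALSE),
                 format(record$end, scientific = FALSE)))
  }
  record$end - record$start
}

#' Read SV records from a TSV
#'
#' Accepts either internal column names (`line_id`, `contig`, `start`,
#' `end`, `sv_type`, ...) or report-style headers (`Group`, `Sample`,
#' `Chromosome`, `Start position`, `End position`, `SVs type`). Type labels
#' `Deletion`/`Duplication`/`Inversion`/`Insertion` map to
#' `DEL`/`DUP`/`INV`/`INS`.
#'
#' @param path Input TSV path.
#' @return SV record data.frame (see [sv_records()]).
#' @export
read_sv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  nm <- tolower(gsub("[ .]", "_", names(df)))
  names(df) <- nm
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% nm) return(df[[cand]])
    NULL
  }
  line_id <- pick("line_id", "sample")
  contig <- pick("contig", "chromosome", "chrom")
  start <- pick("start", "start_position")
  end <- pick("end", "end_position")
  type <- pick("sv_type", "svs_type", "type")
  if (is.null(line_id) || is.null(contig) || is.null(start) ||
      is.null(end) || is.null(type)) {
    stop("SV table needs line/sample, chromosome, start, end and type ",
         "columns")
  }
  long <- c(Deletion = "DEL", Duplication = "DUP", Inversion = "INV",
            Insertion = "INS")
  type <- ifelse(type %in% names(long), long[type], toupper(type))
  genotype <- pick("genotype", "group")
  validated <- pick("validated", "igv_verification")
  validated <- if (is.null(validated)) FALSE else
    validated %in% c("TRUE", "T", "1", "yes", "✓")
  callers <- pick("callers")
  sv_records(line_id, contig, start, end, type,
             callers = if (is.null(callers)) "other" else callers,
             validated = validated,
             genotype = if (is.null(genotype)) NA_character_ else genotype)
}

# reciprocal overlap of intervals [a1,a2] and [b1,b2] (end-exclusive sizes)
reciprocal_overlap <- function(a1, a2, b1, b2) {
  ov <- max(0, min(a2, b2) - max(a1, b1))
  min(ov / (a2 - a1), ov / (b2 - b1))
}

#' Merge per-caller SV call sets into a consensus
#'
#' Same-line, same-type records from different callers whose reciprocal
#' overlap reaches the threshold are merged transitively; merged coordinates
#' are the member medians and the caller set is the union. Clusters
#' supported by fewer than `min_callers` distinct callers are dropped unless
#' any member is `validated`.
#'
#' @param callsets Named list of SV record data.frames, one per caller; the
#'   list names overwrite the `callers` column.
#' @param reciprocal_overlap Minimum reciprocal overlap (default 0.8).
#' @param min_callers Minimum distinct supporting callers (default 2).
#' @return Consensus SV record data.frame.
#' @export
merge_consensus <- function(callsets, reciprocal_overlap = 0.8,
                            min_callers = 2L) {
  if (!is.null(names(callsets))) {
    callsets <- lapply(names(callsets), function(nm) {
      d <- callsets[[nm]]
      if (nrow(d)) d$callers <- nm
      d
    })
  }
  all <- do.call(rbind, callsets)
  if (is.null(all) || nrow(all) == 0L) {
    return(sv_records(character(0), character(0), numeric(0), numeric(0),
                      character(0)))
  }
  ro_min <- reciprocal_overlap
  key <- paste(all$line_id, all$contig, all$sv_type)
  out <- list()
  for (k in unique(key)) {
    grp <- all[key == k, , drop = FALSE]
    n <- nrow(grp)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      ro <- reciprocal_overlap(grp$start[i], grp$end[i],
                               grp$start[j], grp$end[j])
      if (ro >= ro_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      mem <- grp[roots == r, , drop = FALSE]
      callers <- sort(unique(unlist(strsplit(mem$callers, ","))))
      out[[length(out) + 1L]] <- data.frame(
        line_id = mem$line_id[1], contig = mem$contig[1],
        start = round(stats::median(mem$start)),
        end = round(stats::median(mem$end)),
        sv_type = mem$sv_type[1],
        callers = paste(callers, collapse = ","),
        validated = any(mem$validated),
        genotype = mem$genotype[1],
        n_callers = length(callers),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$n_callers >= min_callers | res$validated, , drop = FALSE]
  res$size <- res$end - res$start
  res$n_callers <- NULL
  rownames(res) <- NULL
  res[order(res$line_id, res$contig, res$start), , drop = FALSE]
}

#' Summarize SV records per genotype
#'
#' @param records SV record data.frame carrying a `genotype` column (or
#'   supply `meta` to map `line_id` to genotype).
#' @param meta Optional line metadata with `line_id` and `genotype`.
#' @return Data.frame with per-genotype record count, counts by type,
#'   size range, and deletion fraction.
#' @export
summarize_svs <- function(records, meta = NULL) {
  if (!is.null(meta)) {
    records$genotype <- meta$genotype[match(records$line_id, meta$line_id)]
  }
  if (nrow(records) == 0L) {
    return(data.frame(genotype = character(0), n_sv = integer(0),
                      n_del = integer(0), n_dup = integer(0),
                      n_inv = integer(0), n_ins = integer(0),
                      min_size = numeric(0), max_size = numeric(0),
                      deletion_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(split(records, records$genotype), function(d) {
    data.frame(genotype = d$genotype[1], n_sv = nrow(d),
               n_del = sum(d$sv_type == "DEL"),
               n_dup = sum(d$sv_type == "DUP"),
               n_inv = sum(d$sv_type == "INV"),
               n_ins = sum(d$sv_type == "INS"),
               min_size = min(d$size), max_size = max(d$size),
               deletion_fraction = mean(d$sv_type == "DEL"),
               stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Published SV call set used as a built-in fixture
#'
#' The 20 manually validated SVs reported for the CIB-irradiated lig4-4
#' (18 records) and wild-type (2 records) genotypes, with their printed
#' coordinates and sizes. `size_printed` is the size column as published;
#' the `size` column is recomputed as `end - start`.
#'
#' @return SV record data.frame with an extra `size_printed` column.
#' @export
published_sv_records <- function() {
  rec <- sv_records(
    line_id = c("L1-2", "L1-4", "L1-11", "L1-12", "L1-14", "L1-4", "L1-2",
                "L1-12", "L1-15", "L1-11", "L1-8", "L1-12", "L1-7", "L1-6",
                "L1-9", "L1-13", "L1-7", "L1-7", "3-4", "3-1"),
    contig = c("1", "1", "1", "1", "1", "1", "1", "2", "3", "3", "4", "4",
               "4", "4", "5", "5", "5", "5", "1", "3"),
    start = c(6992317, 10993642, 16939998, 25618829, 27307872, 28491172,
              30164546, 10395128, 19928674, 21916848, 195851, 16040504,
              18179116, 18289363, 1745827, 5531895, 17879971, 20646146,
              21677471, 307505),
    end = c(6992386, 10993984, 16940064, 25618891, 27308242, 28491229,
            30165031, 10395225, 19928724, 21916914, 195942, 16040567,
            18179773, 18289512, 1745882, 5531960, 17880025, 20646201,
            21677532, 326093),
    sv_type = c(rep("DEL", 7), "DUP", rep("DEL", 10), "DEL", "DEL"),
    callers = "lumpy,delly,manta", validated = TRUE,
    genotype = c(rep("lig4-4", 18), rep("WT", 2)))
  rec$size_printed <- c(69, 342, 66, 62, 370, 57, 485, 97, 50, 66, 86, 63,
                        657, 149, 55, 65, 54, 55, 61, 18588)
  rec
}
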