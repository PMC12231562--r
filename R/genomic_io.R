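# Genome, gene-model, and variant-table I/O.
#
# Coordinate convention: 1-based inclusive everywhere in user-facing
# structures (the VCF/GFF3 dialect); internal arithmetic stays on the same
# scale so there is a single convention to reason about.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on read; `N` is allowed. Contig names are the
#' first whitespace-delimited word of each header.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A named character vector, one uppercase nucleotide string per
#'   contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  nm <- vapply(strsplit(names(dss), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate contig names in ", path)
  stats::setNames(seqs, nm)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Total genome length
#'
#' @param genome Named character vector of contig sequences.
#' @return Sum of contig lengths in bp.
#' @export
genome_length <- function(genome) sum(nchar(genome))

# substring of one contig, clipped to the contig bounds; returns "" when the
# clipped window is empty
genome_slice <- function(genome, contig, start, end) {
  s <- genome[[contig]]
  start <- max(1L, as.integer(start))
  end <- min(nchar(s), as.integer(end))
  if (start > end) return("")
  substr(s, start, end)
}

#' Read gene models from GFF3
#'
#' One model per gene is retained: the first mRNA in file order defines the
#' exon/CDS structure (a message is emitted for multi-isoform genes). The
#' transcription start site is the gene's 5' end on its strand.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon/CDS features linked by
#'   `ID`/`Parent` attributes.
#' @return A data.frame with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end`, `tss`, plus list-columns `exons` and `cds` holding data.frames of
#'   1-based inclusive intervals in transcription order (`cds` also carries a
#'   `phase` column).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  if (!"phase" %in% names(df)) df$phase <- NA_integer_

  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    return(empty_gene_models())
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- g$ID
    mrnas <- df[df$type == "mRNA" & df$Parent == gid, , drop = FALSE]
    if (nrow(mrnas) == 0L) {
      stop("gene without mRNA feature: ", gid)
    }
    if (nrow(mrnas) > 1L) {
      message("gene ", gid, ": ", nrow(mrnas),
              " mRNA isoforms; keeping the first in file order")
    }
    m <- mrnas[1L, ]
    ex <- df[df$type == "exon" & df$Parent == m$ID, , drop = FALSE]
    cd <- df[df$type == "CDS" & df$Parent == m$ID, , drop = FALSE]
    minus <- identical(g$strand, "-")
    ord <- order(ex$start, decreasing = minus)
    ex <- ex[ord, , drop = FALSE]
    ordc <- order(cd$start, decreasing = minus)
    cd <- cd[ordc, , drop = FALSE]
    # every CDS interval must lie inside some exon
    ok <- vapply(seq_len(nrow(cd)), function(j)
      any(cd$start[j] >= ex$start & cd$end[j] <= ex$end), logical(1))
    if (!all(ok)) stop("CDS outside exon for gene ", gid)
    list(
      gene_id = gid, contig = g$seqnames, strand = g$strand,
      start = g$start, end = g$end,
      tss = if (minus) g$end else g$start,
      exons = data.frame(start = ex$start, end = ex$end),
      cds = data.frame(start = cd$start, end = cd$end,
                       phase = ifelse(is.na(cd$phase), 0L,
                                      as.integer(cd$phase)))
    )
  })
  data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    contig = vapply(rows, `[[`, character(1), "contig"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    tss = vapply(rows, `[[`, numeric(1), "tss"),
    exons = I(lapply(rows, `[[`, "exons")),
    cds = I(lapply(rows, `[[`, "cds")),
    stringsAsFactors = FALSE
  )
}

empty_gene_models <- function() {
  data.frame(gene_id = character(0), contig = character(0),
             strand = character(0), start = numeric(0), end = numeric(0),
             tss = numeric(0), exons = I(list()), cds = I(list()),
             stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#'
#' @param models Gene-model data.frame as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    gid <- g$gene_id
    mid <- paste0(gid, ".1")
    st <- g$strand
    lines <- c(lines,
      paste(g$contig, "cibmut", "gene", g$start, g$end, ".", st, ".",
            paste0("ID=", gid), sep = "\t"),
      paste(g$contig, "cibmut", "mRNA", g$start, g$end, ".", st, ".",
            paste0("ID=", mid, ";Parent=", gid), sep = "\t"))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
        paste(g$contig, "cibmut", "exon", ex$start[j], ex$end[j], ".", st,
              ".", paste0("ID=", mid, ".exon", j, ";Parent=", mid),
              sep = "\t"))
    }
    cd <- g$cds[[1]]
    for (j in seq_len(nrow(cd))) {
      lines <- c(lines,
        paste(g$contig, "cibmut", "CDS", cd$start[j], cd$end[j], ".", st,
              cd$phase[j], paste0("ID=", mid, ".cds;Parent=", mid),
              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- variant call tables ----------------------------------------------------

# A variant-call table is a data.frame with columns
#   contig, pos, ref, alt, line_id
# plus one numeric column per sequenced line named af_<line_id> holding the
# variant-supporting read fraction of that line at this locus (0 when the
# line shows no support). `line_id` is the carrier/target line of the row.

call_af_cols <- function(calls) grep("^af_", names(calls), value = TRUE)

call_lines <- function(calls) sub("^af_", "", call_af_cols(calls))

#' Construct a variant-call table
#'
#' @param contig,pos,ref,alt,line_id Vectors describing one call per element;
#'   `pos` is the 1-based position of the first REF base.
#' @param af_by_line Numeric matrix of variant-supporting read fractions, one
#'   row per call, one column per sequenced line (column names = line ids).
#'   Defaults to 0.5 for the carrier line and 0 elsewhere.
#' @return A variant-call data.frame.
#' @export
variant_calls <- function(contig, pos, ref, alt, line_id,
                          af_by_line = NULL) {
  n <- length(pos)
  contig <- rep_len(as.character(contig), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  line_id <- rep_len(as.character(line_id), n)
  stopifnot(all(pos >= 1), all(ref != alt))
  if (is.null(af_by_line)) {
    lines <- sort(unique(line_id))
    af_by_line <- matrix(0, n, length(lines),
                         dimnames = list(NULL, lines))
    for (i in seq_len(n)) af_by_line[i, line_id[i]] <- 0.5
  }
  stopifnot(is.matrix(af_by_line), nrow(af_by_line) == n,
            all(af_by_line >= 0 & af_by_line <= 1))
  out <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                    ref = ref, alt = alt, line_id = as.character(line_id),
                    stringsAsFactors = FALSE)
  if (ncol(af_by_line) == 0L) return(out)
  af <- as.data.frame(af_by_line)
  names(af) <- paste0("af_", colnames(af_by_line))
  cbind(out, af)
}

empty_calls <- function(lines = character(0)) {
  variant_calls(character(0), integer(0), character(0), character(0),
                character(0),
                af_by_line = matrix(numeric(0), 0, length(lines),
                                    dimnames = list(NULL, lines)))
}

#' Read small-variant calls from VCF or a tabular call file
#'
#' VCF (`*.vcf`) records must carry a per-sample variant-supporting read
#' fraction, either as `AD` (ref,alt depths; the fraction is
#' `alt/(ref+alt)`) or as a VarScan-style `FREQ` percentage. Multi-allelic
#' records are split into one call per ALT; symbolic ALTs (e.g. `<DEL>`) are
#' skipped with a message (they belong to the SV reader). One call row is
#' emitted per record x carrier line (fraction > 0).
#'
#' Tabular files (anything else) are tab-separated with columns `contig`,
#' `pos`, `ref`, `alt`, `line_id` and either per-line `af_<line>` columns or
#' a single `af` column for the carrier line.
#'
#' @param path Input file.
#' @return A variant-call data.frame (see [variant_calls()]).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_vcf_calls(path)
  } else {
    read_tsv_calls(path)
  }
}

read_tsv_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("contig", "pos", "ref", "alt", "line_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("call table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  afc <- grep("^af_", names(df), value = TRUE)
  if (length(afc)) {
    m <- as.matrix(df[afc])
    colnames(m) <- sub("^af_", "", afc)
  } else if ("af" %in% names(df)) {
    lines <- sort(unique(df$line_id))
    m <- matrix(0, nrow(df), length(lines), dimnames = list(NULL, lines))
    for (i in seq_len(nrow(df))) m[i, df$line_id[i]] <- df$af[i]
  } else {
    stop("call table needs either af_<line> columns or an 'af' column ",
         "with the variant-supporting read fraction")
  }
  variant_calls(df$contig, df$pos, df$ref, df$alt, df$line_id, m)
}

read_vcf_calls <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  samples <- colnames(vcf)
  gen <- VariantAnnotation::geno(vcf)
  has_ad <- "AD" %in% names(gen)
  has_freq <- "FREQ" %in% names(gen)
  if (!has_ad && !has_freq) {
    stop("VCF lacks per-sample allele-fraction information: a FORMAT ",
         "field 'AD' (ref,alt depths) or 'FREQ' (VarScan percentage) ",
         "is required")
  }
  out <- list()
  n_sym <- 0L
  for (i in seq_along(rr)) {
    alts <- as.character(altl[[i]])
    for (k in seq_along(alts)) {
      a <- alts[k]
      if (!grepl("^[ACGTNacgtn]+$", a)) { n_sym <- n_sym + 1L; next }
      af <- vapply(samples, function(s) {
        if (has_ad) {
          ad <- gen$AD[i, s][[1]]
          if (all(is.na(ad))) return(0)
          tot <- sum(ad, na.rm = TRUE)
          if (tot == 0) return(0)
          ad[k + 1L] / tot
        } else {
          f <- gen$FREQ[i, s]
          if (is.na(f) || f == ".") return(0)
          as.numeric(sub("%", "", f)) / 100
        }
      }, numeric(1))
      carriers <- samples[af > 0]
      for (s in carriers) {
        out[[length(out) + 1L]] <- list(
          contig = contig[i], pos = pos[i], ref = ref[i], alt = a,
          line_id = s, af = af)
      }
    }
  }
  if (n_sym > 0L) {
    message(n_sym, " symbolic-ALT record(s) skipped (use the SV reader)")
  }
  if (!length(out)) return(empty_calls(samples))
  m <- do.call(rbind, lapply(out, `[[`, "af"))
  colnames(m) <- samples
  variant_calls(vapply(out, `[[`, character(1), "contig"),
                vapply(out, `[[`, numeric(1), "pos"),
                vapply(out, `[[`, character(1), "ref"),
                vapply(out, `[[`, character(1), "alt"),
                vapply(out, `[[`, character(1), "line_id"), m)
}

#' Write a variant-call table to TSV
#'
#' @param calls Variant-call data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write calls as a minimal multi-sample VCF
#'
#' Allele fractions are encoded as `AD` depths at a nominal total depth, so
#' a round trip through [read_variant_table()] recovers fractions to
#' `1/depth` resolution.
#'
#' @param calls Variant-call data.frame.
#' @param path Output path.
#' @param depth Nominal per-sample read depth used to synthesize `AD`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, depth = 60L) {
  lines <- call_lines(calls)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", lines), collapse = "\t"))
  key <- paste(calls$contig, calls$pos, calls$ref, calls$alt)
  recs <- character(0)
  for (k in unique(key)) {
    rows <- calls[key == k, , drop = FALSE]
    r <- rows[1L, ]
    af <- vapply(lines, function(l) max(rows[[paste0("af_", l)]]),
                 numeric(1))
    ad <- round(af * depth)
    smp <- sprintf("%s:%d,%d", ifelse(ad > 0, "0/1", "0/0"),
                   depth - ad, ad)
    recs <- c(recs, paste(c(r$contig, r$pos, ".", r$ref, r$alt, ".",
                            "PASS", ".", "GT:AD", smp), collapse = "\t"))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# ---- normalization ----------------------------------------------------------

#' Normalize variant representation
#'
#' Trims shared leading/trailing bases, left-aligns InDels (smallest
#' position preserving the alternate haplotype), keeps the single-base VCF
#' anchor for InDels, and decomposes residual multi-nucleotide substitutions
#' into per-base SBS calls. Idempotent.
#'
#' @param calls Variant-call data.frame.
#' @param genome Named character vector of contig sequences; the REF allele
#'   of every call must match the genome at its position.
#' @return A normalized variant-call data.frame (possibly more rows than the
#'   input, due to MNV decomposition).
#' @export
normalize_variants <- function(calls, genome) {
  if (nrow(calls) == 0L) return(calls)
  pieces <- lapply(seq_len(nrow(calls)), function(i) {
    row <- calls[i, , drop = FALSE]
    norm <- normalize_one(row$contig, row$pos, row$ref, row$alt, genome)
    out <- row[rep(1L, nrow(norm)), , drop = FALSE]
    out$pos <- norm$pos
    out$ref <- norm$ref
    out$alt <- norm$alt
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

# normalize a single (contig,pos,ref,alt); returns a data.frame of one or
# more rows (MNVs decompose into per-base SBSs)
normalize_one <- function(contig, pos, ref, alt, genome) {
  seq <- genome[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
    stop(sprintf("reference mismatch at %s:%d (expected %s)",
                 contig, pos, ref))
  }
  # work unanchored: trim shared trailing, then leading, bases fully
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }

  if (nchar(ref) == 0L && nchar(alt) == 0L) {
    stop("ref and alt alleles are identical at ", contig, ":", pos)
  }

  if (nchar(alt) == 0L) {                    # pure deletion of ref at [s,e]
    s <- pos
    e <- pos + nchar(ref) - 1L
    # shifting [s,e] -> [s-1,e-1] preserves the haplotype iff seq[s-1]==seq[e]
    while (s > 2L && substr(seq, s - 1L, s - 1L) == substr(seq, e, e) &&
           substr(seq, e, e) != "N") {
      s <- s - 1L; e <- e - 1L
    }
    if (s > 1L) {
      pos <- s - 1L
      ref <- substr(seq, pos, e)
      alt <- substr(seq, pos, pos)
    } else {                                 # contig start: right-anchor
      pos <- 1L
      ref <- substr(seq, 1L, e + 1L)
      alt <- substr(seq, e + 1L, e + 1L)
    }
    return(data.frame(pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE))
  }

  if (nchar(ref) == 0L) {                    # pure insertion before pos
    ins <- alt
    p <- pos
    # moving the insertion point left by one rotates the last base to front
    while (p > 2L) {
      last <- substr(ins, nchar(ins), nchar(ins))
      if (substr(seq, p - 1L, p - 1L) != last || last == "N") break
      ins <- paste0(last, substr(ins, 1L, nchar(ins) - 1L))
      p <- p - 1L
    }
    if (p > 1L) {
      pos <- p - 1L
      ref <- substr(seq, pos, pos)
      alt <- paste0(ref, ins)
    } else {                                 # contig start: right-anchor
      pos <- 1L
      ref <- substr(seq, 1L, 1L)
      alt <- paste0(ins, ref)
    }
    return(data.frame(pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE))
  }

  if (nchar(ref) == nchar(alt)) {
    if (nchar(ref) == 1L) {                  # SBS
      return(data.frame(pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE))
    }
    rb <- strsplit(ref, "")[[1]]             # MNV: decompose per base
    ab <- strsplit(alt, "")[[1]]
    idx <- which(rb != ab)
    return(data.frame(pos = pos + idx - 1L, ref = rb[idx], alt = ab[idx],
                      stringsAsFactors = FALSE))
  }

  # length-changing substitution (delins): keep trimmed, left-anchored
  if (pos > 1L) {
    anchor <- substr(seq, pos - 1L, pos - 1L)
    return(data.frame(pos = pos - 1L, ref = paste0(anchor, ref),
                      alt = paste0(anchor, alt), stringsAsFactors = FALSE))
  }
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Normalize a single InDel or SBS call
#'
#' Convenience single-call wrapper around [normalize_variants()].
#'
#' @param call One-row variant-call data.frame.
#' @param genome Named character vector of contig sequences.
#' @return The normalized call (one row; MNV inputs are rejected here).
#' @export
normalize_indel <- function(call, genome) {
  out <- normalize_variants(call, genome)
  if (nrow(out) != 1L) {
    stop("call decomposed into multiple SBSs; use normalize_variants()")
  }
  out
}
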