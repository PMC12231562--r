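# Independent brute-force oracles used to check the implementation.

# apply a (pos, ref, alt) variant to a contig string
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# brute-force leftmost equivalent placement of a deletion of `dlen` bases:
# try every start and compare full alternate haplotypes
leftmost_deletion <- function(seq, pos, dlen) {
  target <- paste0(substr(seq, 1L, pos - 1L),
                   substr(seq, pos + dlen, nchar(seq)))
  for (s in seq_len(pos)) {
    cand <- paste0(substr(seq, 1L, s - 1L),
                   substr(seq, s + dlen, nchar(seq)))
    if (cand == target) return(s)
  }
  pos
}

# naive junction-microhomology scan: compare every k explicitly
brute_mh <- function(A, left_flank, right_flank, cap = 20L) {
  best <- 0L; side <- "none"
  kr <- 0L
  for (k in seq_len(min(nchar(A), nchar(right_flank), cap))) {
    piece <- substr(A, 1L, k)
    flank <- substr(right_flank, 1L, k)
    if (piece != flank || grepl("N", piece) || grepl("N", flank)) break
    kr <- k
  }
  kl <- 0L
  for (k in seq_len(min(nchar(A), nchar(left_flank), cap))) {
    piece <- substr(A, nchar(A) - k + 1L, nchar(A))
    flank <- substr(left_flank, nchar(left_flank) - k + 1L,
                    nchar(left_flank))
    if (piece != flank || grepl("N", piece) || grepl("N", flank)) break
    kl <- k
  }
  best <- max(kr, kl)
  side <- if (best == 0L) "none" else if (kr == best && kl == best) "both"
    else if (kr == best) "right" else "left"
  list(mh_len = best, mh_side = side)
}

# O(window^2) tandem-array scan: every unit length, every start, extend a
# perfect array and test junction coverage; shortest unit wins
brute_tandem <- function(region, ja, jb, unit_min = 2L, unit_max = 10L,
                         min_copies = 2L) {
  n <- nchar(region)
  for (u in unit_min:unit_max) {
    for (s in seq_len(n - u * min_copies + 1L)) {
      unit <- substr(region, s, s + u - 1L)
      if (grepl("N", unit)) next
      if (length(unique(strsplit(unit, "")[[1]])) == 1L) next
      e <- s + u - 1L
      while (e + u <= n && substr(region, e + 1L, e + u) == unit) {
        e <- e + u
      }
      # extend by partial trailing matches of the unit period
      ee <- e
      while (ee < n &&
             substr(region, ee + 1L, ee + 1L) ==
             substr(region, ee + 1L - u, ee + 1L - u)) {
        ee <- ee + 1L
      }
      if ((ee - s + 1L) >= u * min_copies && s <= ja && ee >= jb) {
        return(unit)
      }
    }
  }
  NA_character_
}

# union-find clustering oracle over the footprint-gap <= window relation
brute_clusters <- function(pos, ref, window = 10L) {
  n <- length(pos)
  start <- pos
  end <- pos + nchar(ref) - 1L
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    gap <- max(start[i], start[j]) - min(end[i], end[j])
    if (gap <= window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# random genome string
random_genome <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# tiny line metadata helper
toy_meta <- function(lines, genotype = "G1", dose = 100) {
  data.frame(line_id = lines, genotype = genotype, dose = dose,
             stringsAsFactors = FALSE)
}

# an empty variant-call table over no lines
empty_calls_fixture <- function() {
  variant_calls(character(0), integer(0), character(0), character(0),
                character(0))
}
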