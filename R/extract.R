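#' Extract repeat tract length distributions from sequence
#'
#' Scans a nucleotide sequence for maximal uninterrupted tracts of simple
#' tandem repeats and tallies one count per maximal repeated region per motif
#' class, with the tract length `L` equal to the maximal number of complete
#' motif units over the phase offsets (partial units at tract ends are
#' ignored).  Single occurrences of a motif that cannot be extended by a
#' complete in-phase unit on either side are counted at `L = 1`, except where
#' the window lies entirely inside an already-counted repeated region of the
#' same period.  `N` and any other non-ACGT symbol terminate tracts.
#'
#' @param sequence A single character string over A/C/G/T/N (case
#'   insensitive).
#' @param unit_lengths Integer vector of motif unit lengths (1-6) to scan.
#' @param reverse_complement If `TRUE` (the default, matching genome-scale
#'   practice where the two strands are indistinguishable), cyclic
#'   permutations of a motif and of its reverse complement are pooled into
#'   one class; if `FALSE` only cyclic permutations are pooled, so e.g. A and
#'   T runs are tallied separately.
#' @param source Provenance string stored in each returned [drl()].
#' @return A named list of [drl()] objects, one per motif class of the
#'   requested unit lengths (classes with no occurrences have empty counts).
#' @examples
#' extract_drl("CAGCAGCAG", unit_lengths = 3)$AGC$counts  # one tract, L = 3
#' @export
extract_drl <- function(sequence, unit_lengths = 1L,
                        reverse_complement = TRUE, source = "") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  stopifnot(all(unit_lengths >= 1L), all(unit_lengths <= 6L))
  seq_up <- toupper(sequence)
  code <- .seq_codes(seq_up)
  n <- length(code)

  tallies <- list() # label -> named numeric (length -> count)
  add <- function(label, lens, counts) {
    if (!length(lens)) return()
    cur <- tallies[[label]]
    if (is.null(cur)) cur <- numeric(0)
    m <- max(lens, length(cur))
    new <- numeric(m)
    new[seq_along(cur)] <- cur
    new[lens] <- new[lens] + counts
    tallies[[label]] <<- new
  }

  for (k in sort(unique(as.integer(unit_lengths)))) {
    if (n < k) next
    ok <- code > 0L
    nw <- n - k + 1L # number of k-windows
    covered <- logical(n)
    if (n > k) {
      cmp <- code[1:(n - k)] == code[(k + 1L):n] &
        ok[1:(n - k)] & ok[(k + 1L):n]
      r <- rle(cmp)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      reg <- which(r$values & r$lengths >= k)
      if (length(reg)) {
        rs <- starts[reg]
        rl <- r$lengths[reg]
        units <- (rl + k) %/% k
        kmers <- substring(seq_up, rs, rs + k - 1L)
        labs <- .kmer_labels(kmers, reverse_complement)
        keep <- !is.na(labs)
        if (any(keep)) {
          covered[sequence(rl[keep] + k, from = rs[keep])] <- TRUE
          tb <- tapply(rep(1, sum(keep)),
                       list(labs[keep], units[keep]), sum)
          for (lab in rownames(tb)) {
            col <- tb[lab, ]
            nz <- !is.na(col)
            add(lab, as.integer(colnames(tb))[nz], as.numeric(col[nz]))
          }
        }
      }
      # in-phase extendability of each window (all k comparisons true)
      csn <- c(0L, cumsum(!cmp))
      ext_f <- logical(nw)
      idx <- seq_len(max(0L, length(cmp) - k + 1L))
      if (length(idx)) ext_f[idx] <- (csn[idx + k] - csn[idx]) == 0L
      ext_b <- logical(nw)
      if (nw > k) ext_b[(k + 1L):nw] <- ext_f[seq_len(nw - k)]
    } else {
      ext_f <- ext_b <- logical(nw)
    }
    cso <- c(0L, cumsum(!ok))
    valid_win <- (cso[seq_len(nw) + k] - cso[seq_len(nw)]) == 0L
    csc <- c(0L, cumsum(covered))
    cov_all <- (csc[seq_len(nw) + k] - csc[seq_len(nw)]) == k
    counted <- valid_win & !ext_f & !ext_b & !cov_all
    pos <- which(counted)
    if (length(pos)) {
      kmers <- substring(seq_up, pos, pos + k - 1L)
      labs <- .kmer_labels(kmers, reverse_complement)
      keep <- !is.na(labs)
      if (any(keep)) {
        tb <- table(labs[keep])
        for (lab in names(tb)) add(lab, 1L, as.numeric(tb[[lab]]))
      }
    }
  }

  out <- list()
  for (k in sort(unique(as.integer(unit_lengths)))) {
    classes <- if (reverse_complement) motif_classes_of_length(k)
               else .rotation_classes_of_length(k)
    for (cl in classes) {
      cts <- tallies[[cl$label]]
      if (is.null(cts)) cts <- numeric(0)
      out[[cl$label]] <- drl(cts, motif = cl, source = source)
    }
  }
  out
}

# byte codes: A=1, C=2, G=3, T=4, anything else 0
.seq_codes <- function(seq_up) {
  map <- integer(256)
  map[as.integer(charToRaw("A")) + 1L] <- 1L
  map[as.integer(charToRaw("C")) + 1L] <- 2L
  map[as.integer(charToRaw("G")) + 1L] <- 3L
  map[as.integer(charToRaw("T")) + 1L] <- 4L
  map[as.integer(charToRaw(seq_up)) + 1L]
}

# canonical labels for a vector of k-mers; NA for non-primitive units
.kmer_labels <- function(kmers, reverse_complement) {
  u <- unique(kmers)
  lab <- vapply(u, function(m) {
    if (!is_primitive_motif(m)) return(NA_character_)
    if (reverse_complement) min(c(rotations(m), rotations(revcomp(m))))
    else min(rotations(m))
  }, character(1))
  unname(lab[match(kmers, u)])
}

# rotation-only classes (no reverse-complement pooling)
.rotation_classes_of_length <- function(k) {
  alph <- c("A", "C", "G", "T")
  grids <- do.call(expand.grid,
                   c(rep(list(alph), k), list(stringsAsFactors = FALSE)))
  motifs <- do.call(paste0, grids)
  motifs <- motifs[vapply(motifs, is_primitive_motif, logical(1))]
  labels <- unique(vapply(motifs, function(m) min(rotations(m)), character(1)))
  lapply(sort(labels), function(lb) {
    structure(list(label = lb, unit_length = k, members = sort(rotations(lb))),
              class = "motif_class")
  })
}

#' Histogram of non-motif ("B") stretch lengths
#'
#' Tallies the lengths (in nt) of maximal stretches of valid sequence in
#' which the given motif does not occur, i.e. runs of positions at which no
#' occurrence of the motif starts.  This is the length distribution of the
#' "B strings" of the binary repeat/non-repeat genome abstraction used by the
#' dynamics.  With `pool_members = TRUE` the histograms obtained for every
#' member of the motif's equivalence class are summed.
#'
#' @param sequence A single character string.
#' @param motif A motif string or `motif_class`.
#' @param pool_members Sum histograms over all class members (default
#'   `FALSE`: the given motif orientation only).
#' @return A named numeric vector: element `"k"` counts non-motif stretches
#'   of length `k` nt.
#' @export
extract_nonmotif_histogram <- function(sequence, motif, pool_members = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.character(motif)) motif <- canonical_label(motif)
  members <- if (pool_members) motif$members else motif$label
  seq_up <- toupper(sequence)
  code <- .seq_codes(seq_up)
  n <- length(code)
  out <- numeric(0)
  for (m in members) {
    k <- nchar(m)
    if (n == 0L) next
    starts_here <- logical(n)
    if (n >= k) {
      nw <- n - k + 1L
      hit <- substring(seq_up, seq_len(nw), seq_len(nw) + k - 1L) == m
      starts_here[seq_len(nw)] <- hit
    }
    bmask <- (code > 0L) & !starts_here
    r <- rle(bmask)
    lens <- r$lengths[r$values]
    if (length(lens)) {
      mx <- max(lens, length(out))
      new <- numeric(mx)
      new[seq_along(out)] <- out
      tb <- tabulate(lens, nbins = mx)
      out <- new + tb
    }
  }
  if (length(out)) names(out) <- seq_along(out)
  out[out > 0]
}

#' Randomly shuffled control sequence
#'
#' Uniform random permutation of the bases of a sequence; base composition is
#' preserved exactly.  The repeat content of the shuffled control is the
#' random-sequence expectation against which genomic repeat excess is judged.
#'
#' @param sequence A single character string.
#' @param seed Integer seed for reproducibility.
#' @return The shuffled sequence (single string).
#' @export
shuffle_control <- function(sequence, seed = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  withr_seed(seed)
  paste(sample(chars), collapse = "")
}

# minimal local RNG scoping (avoid a withr dependency)
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

#' Segment-bootstrap confidence intervals for a DRL
#'
#' Splits the sequence into contiguous non-overlapping segments (discarding
#' any trailing sub-segment), measures the DRL per segment, reconstitutes
#' genome-scale DRLs by resampling segments with replacement, and forms
#' per-bin intervals by dropping the most extreme replicate values (25 at
#' each end for 1000 replicates, scaled proportionally otherwise) and taking
#' the min and max of what remains.
#'
#' @param sequence A single character string.
#' @param motif Motif class (or label) whose DRL is bootstrapped.
#' @param segment_length Segment size in nt (default 1e6).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param reverse_complement Passed to [extract_drl()].
#' @return A list with dense vectors `lo` and `hi` (per-length bounds), the
#'   number of replicates dropped per side (`n_drop`), and the observed
#'   full-sequence counts (`observed`).
#' @export
bootstrap_ci <- function(sequence, motif = "A", segment_length = 1e6,
                         n_boot = 1000L, seed = 1L,
                         reverse_complement = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.character(motif)) motif <- canonical_label(motif)
  n <- nchar(sequence)
  nseg <- floor(n / segment_length)
  if (nseg < 1L)
    stop("insufficient data: no complete segment of ", segment_length,
         " nt", call. = FALSE)
  seg_counts <- lapply(seq_len(nseg), function(i) {
    s <- substr(sequence, (i - 1L) * segment_length + 1L, i * segment_length)
    extract_drl(s, unit_lengths = motif$unit_length,
                reverse_complement = reverse_complement)[[motif$label]]$counts
  })
  maxL <- max(1L, vapply(seg_counts, length, integer(1)))
  mat <- vapply(seg_counts, function(x) { length(x) <- maxL; x[is.na(x)] <- 0; x },
                numeric(maxL))
  mat <- matrix(mat, nrow = maxL)
  withr_seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    pick <- sample.int(nseg, nseg, replace = TRUE)
    rowSums(mat[, pick, drop = FALSE])
  }, numeric(maxL))
  reps <- matrix(reps, nrow = maxL)
  n_drop <- floor(25 * n_boot / 1000)
  bounds <- apply(reps, 1L, function(v) {
    v <- sort(v)
    if (n_drop > 0) v <- v[(n_drop + 1L):(length(v) - n_drop)]
    c(min(v), max(v))
  })
  list(lo = bounds[1L, ], hi = bounds[2L, ], n_drop = n_drop,
       observed = rowSums(mat))
}
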