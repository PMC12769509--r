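#' Repeat tract length distributions (DRLs)
#'
#' A DRL stores, for one motif class, the genome-wide counts of maximal
#' uninterrupted repeat tracts at each tract length (in motif units).  It is
#' the central object of the pipeline: extracted from sequence, evolved by the
#' mutation kernel, and compared by the inference machinery.
#'
#' @param counts Numeric vector of counts.  Either dense (element `L` is the
#'   count at tract length `L`) or sparse with names giving the lengths.
#' @param motif A `motif_class`, or a motif string passed to
#'   [canonical_label()].
#' @param source Free-text provenance (assembly name, synthetic seed, ...).
#' @return An object of class `drl` with fields `motif`, `counts` (dense,
#'   `counts[L]` is the count at length `L`), and `source`.
#' @export
drl <- function(counts, motif = "A", source = "") {
  if (is.character(motif)) motif <- canonical_label(motif)
  if (!is.null(names(counts))) {
    lens <- as.integer(names(counts))
    if (anyNA(lens) || any(lens < 1L))
      stop("sparse DRL counts must be named by integer lengths >= 1", call. = FALSE)
    dense <- numeric(if (length(lens)) max(lens) else 0L)
    dense[lens] <- as.numeric(counts)
    counts <- dense
  }
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts))
    stop("DRL counts must be nonnegative and finite", call. = FALSE)
  structure(list(motif = motif, counts = counts, source = source),
            class = "drl")
}

#' @export
print.drl <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat("<drl> class ", x$motif$label, ", ", length(nz), " populated bins",
      if (length(nz)) paste0(" (L = ", min(nz), "..", max(nz), ")"),
      if (nzchar(x$source)) paste0(" [", x$source, "]"), "\n", sep = "")
  invisible(x)
}

drl_total <- function(d, L_min = 1L) {
  cts <- d$counts
  if (L_min > length(cts)) return(0)
  sum(cts[L_min:length(cts)])
}

#' Conditional normalization of a DRL
#'
#' Divides counts by the total over length classes `L >= L_min`, yielding the
#' conditional probability distribution P(L | L >= L_min).  Bins below
#' `L_min` get probability zero.  Comparing assemblies of different total
#' size requires this normalization.
#'
#' @param d A [drl()].
#' @param L_min Minimum length included in the normalization.
#' @return An object of class `normalized_drl` with fields `motif`, `L_min`,
#'   `probs` (dense vector; `probs[L]` is the probability at length `L`) and
#'   `total` (the count total used, so [rescale_to()] can invert).
#' @export
normalize_drl <- function(d, L_min = 1L) {
  stopifnot(inherits(d, "drl"), L_min >= 1L)
  tot <- drl_total(d, L_min)
  if (tot <= 0)
    stop("degenerate distribution: no counts at L >= ", L_min, call. = FALSE)
  probs <- d$counts
  if (L_min > 1L) probs[seq_len(L_min - 1L)] <- 0
  probs <- probs / tot
  structure(list(motif = d$motif, L_min = as.integer(L_min), probs = probs,
                 total = tot, source = d$source),
            class = "normalized_drl")
}

#' Rescale a normalized DRL back to counts
#'
#' @param nd A `normalized_drl`.
#' @param total Reference total count over `L >= L_min` (defaults to the
#'   total recorded at normalization, giving an exact round trip).
#' @return A [drl()] whose counts on `L >= L_min` equal `probs * total`.
#' @export
rescale_to <- function(nd, total = nd$total) {
  stopifnot(inherits(nd, "normalized_drl"))
  drl(nd$probs * total, motif = nd$motif, source = nd$source)
}

#' Truncate a DRL above the first under-populated bin
#'
#' Removes all bins at and above the smallest length whose count falls below
#' `threshold`, so that assemblies are only compared on length classes robust
#' to statistical noise.
#'
#' @param d A [drl()].
#' @param threshold Count threshold (default 30).
#' @return A [drl()] with the truncated counts.
#' @export
truncate_low_counts <- function(d, threshold = 30) {
  stopifnot(inherits(d, "drl"))
  cts <- d$counts
  low <- which(cts < threshold)
  if (length(low)) cts <- cts[seq_len(low[1L] - 1L)]
  drl(cts, motif = d$motif, source = d$source)
}

#' Per-bin median of an ensemble of normalized DRLs
#'
#' Used to summarize a taxonomic group: for each length bin, take the value of
#' the median member.  For an even-sized ensemble the mean of the two central
#' values is used.  The result is a per-bin summary and is not renormalized
#' (its bins need not sum to one).
#'
#' @param ensemble List of `normalized_drl` objects (same motif class).
#' @return A `normalized_drl`-like object holding the per-bin medians.
#' @export
median_drl <- function(ensemble) {
  stopifnot(length(ensemble) >= 1L)
  maxL <- max(vapply(ensemble, function(e) length(e$probs), integer(1)))
  mat <- vapply(ensemble, function(e) {
    p <- e$probs
    length(p) <- maxL
    p[is.na(p)] <- 0
    p
  }, numeric(maxL))
  med <- apply(matrix(mat, nrow = maxL), 1L, stats::median)
  structure(list(motif = ensemble[[1L]]$motif,
                 L_min = ensemble[[1L]]$L_min,
                 probs = med, total = NA_real_, source = "median"),
            class = "normalized_drl")
}
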