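#' Generate labelled de novo mutation events
#'
#' Samples synthetic indel events from a genome's repeat content under given
#' instability-rate curves, with truth labels, for exercising the event
#' classifier and the length-stratified rate estimator.  Event counts per
#' (process, parent length) are Poisson with mean
#' rate(L) x target(L) x denominator(L) x n_genomes, where the targets are
#' L for expansion and contraction and L-1 for non-motif insertion.  Each
#' event carries reference flanks that embed the full parent tract.
#'
#' @param curve A [rate_curve()]: generating expansion/contraction/insertion
#'   rates.
#' @param subst A [substitution_rates()] (unused by the indel generator but
#'   kept alongside for provenance).
#' @param genome A [drl()] of parent tract counts (the rate denominators),
#'   or a sequence string from which the mono-A DRL is extracted.
#' @param n_genomes Number of offspring genomes observed.
#' @param seed Integer seed.
#' @param flank_pad Number of non-motif bases padding each flank.
#' @return A data frame with columns `kind` (insertion/deletion), `ref`,
#'   `alt`, `flank_left`, `flank_right`, and truth columns `truth_category`,
#'   `truth_unit_delta`, `truth_parent`.
#' @export
generate_trio_events <- function(curve, subst = substitution_rates(),
                                 genome, n_genomes = 1e3, seed = 1L,
                                 flank_pad = 6L) {
  if (is.character(genome))
    genome <- extract_drl(genome, 1L)[["A"]]
  stopifnot(inherits(genome, "drl"))
  withr_seed(seed)
  denom <- genome$counts
  Lmax <- min(length(denom), length(curve$eps))
  L <- seq_len(Lmax)
  mk <- function(n_by_L, category) {
    Ls <- rep(L, n_by_L)
    if (!length(Ls)) return(NULL)
    data.frame(truth_parent = Ls, truth_category = category)
  }
  n_exp <- stats::rpois(Lmax, curve$eps[L] * L * denom[L] * n_genomes)
  n_con <- stats::rpois(Lmax, curve$kap[L] * L * denom[L] * n_genomes *
                          (L >= 2))
  n_ins <- stats::rpois(Lmax, curve$iota[L] * pmax(L - 1, 0) * denom[L] *
                          n_genomes)
  ev <- rbind(mk(n_exp, "expansion"), mk(n_con, "contraction"),
              mk(n_ins, "non_motif_insertion"))
  if (is.null(ev))
    return(data.frame(kind = character(), ref = character(),
                      alt = character(), flank_left = character(),
                      flank_right = character(),
                      truth_category = character(),
                      truth_unit_delta = integer(),
                      truth_parent = integer()))
  n <- nrow(ev)
  ev <- ev[sample.int(n), , drop = FALSE]
  P <- ev$truth_parent
  pad <- strrep("C", flank_pad)
  pos <- integer(n)
  is_exp <- ev$truth_category == "expansion"
  is_con <- ev$truth_category == "contraction"
  is_ins <- ev$truth_category == "non_motif_insertion"
  # expansion: insertion point uniform on 0..L (left tail = pos)
  pos[is_exp] <- vapply(P[is_exp], function(p) sample.int(p + 1L, 1L) - 1L,
                        integer(1))
  # contraction: deleted unit uniform on 1..L (left tail = pos - 1)
  pos[is_con] <- vapply(P[is_con], function(p) sample.int(p, 1L), integer(1))
  # non-motif insertion: interior junction uniform on 1..L-1
  pos[is_ins] <- vapply(P[is_ins], function(p) sample.int(p - 1L, 1L),
                        integer(1))
  left_tail <- ifelse(is_con, pos - 1L, pos)
  ref <- ifelse(is_con, "A", "")
  alt <- ifelse(is_exp, "A",
                ifelse(is_ins, sample(c("C", "G", "T"), n, replace = TRUE),
                       ""))
  right_tail <- P - pos
  data.frame(kind = ifelse(is_con, "deletion", "insertion"),
             ref = ref, alt = alt,
             flank_left = paste0(pad, strrep("A", left_tail)),
             flank_right = paste0(strrep("A", right_tail), pad),
             truth_category = ev$truth_category,
             truth_unit_delta = ifelse(is_exp, 1L, ifelse(is_con, -1L, 0L)),
             truth_parent = P,
             stringsAsFactors = FALSE)
}

#' Classify an indel event relative to a repeat tract
#'
#' Determines whether an indel is a whole-unit expansion, a whole-unit
#' contraction, a non-motif insertion interrupting a tract (fission), a
#' partial deletion, or none of these, together with the signed change in
#' units and the parent tract length.  Indels are left-aligned within the
#' tract before classification, so placement ambiguity inside a perfect
#' tract is resolved deterministically.
#'
#' @param kind "insertion", "deletion" or "substitution".
#' @param ref,alt Deleted / inserted sequence (empty string for the absent
#'   side of an indel).
#' @param flank_left,flank_right Reference sequence flanking the event,
#'   long enough to contain the whole parent tract.
#' @param motif A motif string or `motif_class` (the classifier is exact for
#'   mononucleotide classes and handles clean multi-unit-motif events).
#' @return A list with `category`, `unit_delta`, `parent_tract_length`.
#' @export
classify_indel_event <- function(kind, ref, alt, flank_left, flank_right,
                                 motif = "A") {
  if (is.character(motif)) motif <- canonical_label(motif)
  if (motif$unit_length == 1L)
    return(as.list(classify_indel_events(
      data.frame(kind = kind, ref = ref, alt = alt,
                 flank_left = flank_left, flank_right = flank_right,
                 stringsAsFactors = FALSE), motif)[1L, ]))
  .classify_general(kind, ref, alt, flank_left, flank_right, motif)
}

#' Vectorized indel classification for mononucleotide motifs
#'
#' @param events Data frame with columns `kind`, `ref`, `alt`,
#'   `flank_left`, `flank_right`.
#' @param motif Mononucleotide `motif_class` (or string).
#' @return A data frame with `category`, `unit_delta`,
#'   `parent_tract_length` aligned with `events`.
#' @export
classify_indel_events <- function(events, motif = "A") {
  if (is.character(motif)) motif <- canonical_label(motif)
  stopifnot(motif$unit_length == 1L)
  M <- motif$label
  lt <- nchar(sub(paste0("^(.*?)(", M, "*)$"), "\\2", events$flank_left))
  rh <- nchar(sub(paste0("^(", M, "*).*$"), "\\1", events$flank_right))
  ref_n <- nchar(events$ref)
  alt_n <- nchar(events$alt)
  ref_allM <- !grepl(paste0("[^", M, "]"), events$ref)
  alt_allM <- !grepl(paste0("[^", M, "]"), events$alt)
  category <- rep("other", nrow(events))
  unit_delta <- integer(nrow(events))
  parent <- lt + rh

  ins <- events$kind == "insertion" & ref_n == 0L & alt_n > 0L
  expn <- ins & alt_allM & parent >= 1L
  category[expn] <- "expansion"
  unit_delta[expn] <- alt_n[expn]

  nmi <- ins & !alt_allM & lt >= 1L & rh >= 1L
  category[nmi] <- "non_motif_insertion"

  del <- events$kind == "deletion" & alt_n == 0L & ref_n > 0L
  con <- del & ref_allM
  category[con] <- "contraction"
  unit_delta[con] <- -ref_n[con]
  parent[del & ref_allM] <- lt[con] + ref_n[con] + rh[con]
  pd <- del & !ref_allM & grepl(M, events$ref, fixed = TRUE) &
    (lt >= 1L | rh >= 1L)
  category[pd] <- "partial_deletion"

  data.frame(category = category, unit_delta = unit_delta,
             parent_tract_length = parent)
}

# spans of class tracts (start, end, units) in a sequence, for one class
.class_tract_spans <- function(seq_str, motif) {
  k <- motif$unit_length
  n <- nchar(seq_str)
  if (n < k) return(data.frame(start = integer(), end = integer(),
                               units = integer()))
  code <- .seq_codes(toupper(seq_str))
  spans <- list()
  if (n > k) {
    cmp <- code[1:(n - k)] == code[(k + 1L):n] & code[1:(n - k)] > 0L &
      code[(k + 1L):n] > 0L
    r <- rle(cmp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= k)) {
      s <- starts[j]
      unit <- substr(seq_str, s, s + k - 1L)
      if (!is_primitive_motif(unit)) next
      if (!(unit %in% motif$members)) next
      spans[[length(spans) + 1L]] <-
        data.frame(start = s, end = s + r$lengths[j] + k - 1L,
                   units = (r$lengths[j] + k) %/% k)
    }
  }
  # single units (L = 1) of any member
  nw <- n - k + 1L
  win <- substring(toupper(seq_str), seq_len(nw), seq_len(nw) + k - 1L)
  hit <- which(win %in% motif$members)
  covered <- rep(FALSE, n)
  for (sp in spans) covered[sp$start:sp$end] <- TRUE
  for (p in hit) {
    if (all(!covered[p:(p + k - 1L)])) {
      ext_f <- p + 2L * k - 1L <= n &&
        substr(seq_str, p + k, p + 2L * k - 1L) == substr(seq_str, p, p + k - 1L)
      ext_b <- p - k >= 1L &&
        substr(seq_str, p - k, p - 1L) == substr(seq_str, p, p + k - 1L)
      if (!ext_f && !ext_b)
        spans[[length(spans) + 1L]] <-
          data.frame(start = p, end = p + k - 1L, units = 1L)
    }
  }
  if (!length(spans)) return(data.frame(start = integer(), end = integer(),
                                        units = integer()))
  do.call(rbind, spans)
}

# general-unit-length classifier (single event)
.classify_general <- function(kind, ref, alt, flank_left, flank_right,
                              motif) {
  u <- motif$unit_length
  wref <- paste0(flank_left, ref, flank_right)
  walt <- paste0(flank_left, alt, flank_right)
  es <- nchar(flank_left) + 1L
  ee <- nchar(flank_left) + max(nchar(ref), 1L)
  sp_ref <- .class_tract_spans(wref, motif)
  sp_alt <- .class_tract_spans(walt, motif)
  touch <- sp_ref$end >= es - 1L & sp_ref$start <= ee + 1L
  parent <- if (any(touch)) max(sp_ref$units[touch]) else 0L
  out <- function(cat, delta) list(category = cat, unit_delta = delta,
                                   parent_tract_length = parent)
  near_alt <- sp_alt$end >= es - 1L & sp_alt$start <= es + nchar(alt) + 1L
  if (kind == "insertion" && nchar(alt) > 0L) {
    if (parent >= 1L && nchar(alt) %% u == 0L &&
        any(sp_alt$units[near_alt] == parent + nchar(alt) / u))
      return(out("expansion", nchar(alt) / u))
    if (parent >= 2L && sum(near_alt) >= 2L &&
        sum(sp_alt$units[near_alt]) <= parent + 1L)
      return(out("non_motif_insertion", 0L))
    return(out("other", 0L))
  }
  if (kind == "deletion" && nchar(ref) > 0L) {
    if (parent >= 1L && nchar(ref) %% u == 0L &&
        (any(sp_alt$units[near_alt] == parent - nchar(ref) / u) ||
         parent - nchar(ref) / u == 0L))
      return(out("contraction", -nchar(ref) / u))
    if (parent >= 1L) return(out("partial_deletion", 0L))
    return(out("other", 0L))
  }
  out("other", 0L)
}

#' Length-stratified instability rate estimation
#'
#' Estimates per-target, per-generation rates for each indel process by
#' dividing observed event counts at each parent tract length by the number
#' of parent tracts at that length, the number of offspring genomes, and the
#' process target size (L for expansions and contractions, L-1 for non-motif
#' insertions).  95% confidence intervals come from Poisson resampling of
#' the counts: `n_rep` replicates per bin, the top and bottom `n_drop`
#' dropped, and the min/max of the retained values taken.
#'
#' @param events Data frame with columns `category` and
#'   `parent_tract_length` (e.g. the output of [classify_indel_events()],
#'   or [generate_trio_events()] truth columns renamed).
#' @param denominators A [drl()] of parent tract counts.
#' @param n_offspring_genomes Number of offspring genomes in the dataset.
#' @param n_rep,n_drop Poisson replicates and per-side drop count.
#' @param seed Seed for the CI resampling.
#' @return A data frame with `process`, `tract_length_units`, `count`,
#'   `rate`, `ci_lo`, `ci_hi`; bins with zero denominator get `NA` rates
#'   (undefined, not zero).
#' @export
estimate_length_stratified_rates <- function(events, denominators,
                                             n_offspring_genomes,
                                             n_rep = 200L, n_drop = 5L,
                                             seed = 1L) {
  stopifnot(inherits(denominators, "drl"))
  withr_seed(seed)
  denom <- denominators$counts
  procs <- c(expansion = "expansion", contraction = "contraction",
             non_motif_insertion = "non_motif_insertion")
  out <- list()
  for (p in names(procs)) {
    sel <- events$category == p
    if (!any(sel) && p != "expansion" && p != "contraction" &&
        p != "non_motif_insertion") next
    Lmax <- length(denom)
    counts <- tabulate(pmin(events$parent_tract_length[sel], Lmax),
                       nbins = Lmax)
    L <- seq_len(Lmax)
    target <- if (p == "non_motif_insertion") pmax(L - 1, 0) else L
    scale <- denom * n_offspring_genomes * target
    rate <- ifelse(scale > 0, counts / scale, NA_real_)
    lo <- hi <- rep(NA_real_, Lmax)
    okbin <- scale > 0
    for (i in which(okbin)) {
      reps <- stats::rpois(n_rep, counts[i]) / scale[i]
      reps <- sort(reps)
      if (n_drop > 0) reps <- reps[(n_drop + 1L):(length(reps) - n_drop)]
      lo[i] <- min(reps); hi[i] <- max(reps)
    }
    out[[p]] <- data.frame(process = p, tract_length_units = L,
                           count = counts, rate = rate,
                           ci_lo = lo, ci_hi = hi)
  }
  do.call(rbind, out)
}
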