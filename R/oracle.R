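#' Random genome generator
#'
#' I.i.d. random sequence at a given motif-unit fraction.  The two-letter
#' alphabet uses "A" for the focal repeat unit and "C" for everything else
#' (the binary A/B abstraction); the four-letter alphabet draws C, G, T
#' uniformly for non-A sites.
#'
#' @param G Genome length in nt (>= 1e3 recommended for any statistics).
#' @param p_A Probability of the repeat unit at each site.
#' @param alphabet "two_letter" or "four_letter".
#' @param seed Integer seed.
#' @return A single character string.
#' @export
generate_genome <- function(G, p_A = 0.37, alphabet = c("two_letter", "four_letter"),
                            seed = 1L) {
  alphabet <- match.arg(alphabet)
  stopifnot(G >= 1, p_A >= 0, p_A < 1)
  withr_seed(seed)
  if (alphabet == "two_letter") {
    chars <- sample(c("A", "C"), G, replace = TRUE, prob = c(p_A, 1 - p_A))
  } else {
    chars <- sample(c("A", "C", "G", "T"), G, replace = TRUE,
                    prob = c(p_A, rep((1 - p_A) / 3, 3)))
  }
  paste(chars, collapse = "")
}

# ---- run-length representation of a binary (A vs non-A) genome -------------
# The genome is treated as circular so that every tract has exactly two
# boundaries, matching the kernel's assumptions; runs alternate A/B.

runs_from_sequence <- function(sequence, a_char = "A") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  isa <- chars == a_char
  r <- rle(isa)
  len <- as.numeric(r$lengths)
  va <- r$values
  if (length(len) > 1L && va[1L] == va[length(va)]) { # circular merge
    len[1L] <- len[1L] + len[length(len)]
    len <- len[-length(len)]
    va <- va[-length(va)]
  }
  list(len = len, isa = va,
       hA = .runs_hist(len[va]), hB = .runs_hist(len[!va]))
}

.runs_hist <- function(lens, nbins = max(1, lens, 0)) {
  if (!length(lens)) return(numeric(1))
  tabulate(as.integer(lens), nbins = max(as.integer(lens)))
}

.hist_add <- function(h, L, d) {
  L <- as.integer(L)
  if (L > length(h)) h <- c(h, numeric(L - length(h)))
  h[L] <- h[L] + d
  h
}

# replace the circular block of consecutive run indices `idx` (already
# normalized, possibly wrapping) by new runs, updating histograms
.replace_block <- function(rs, idx, newlen, newisa) {
  n <- length(rs$len)
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (rs$isa[i]) rs$hA <- .hist_add(rs$hA, rs$len[i], -1)
    else rs$hB <- .hist_add(rs$hB, rs$len[i], -1)
  }
  if (length(idx) > 1L && any(diff(idx) != 1L)) {
    # wrapping block: rotate the run vectors so the block becomes contiguous
    start <- idx[!(.circ(idx - 1L, n) %in% idx)]
    shift <- start[1L] - 1L
    ord <- c((shift + 1L):n, seq_len(shift))
    rs$len <- rs$len[ord]
    rs$isa <- rs$isa[ord]
    idx <- sort(.circ(idx - shift, n))
  }
  lo <- min(idx); hi <- max(idx)
  head_len <- if (lo > 1L) rs$len[seq_len(lo - 1L)] else numeric(0)
  head_isa <- if (lo > 1L) rs$isa[seq_len(lo - 1L)] else logical(0)
  tail_len <- if (hi < n) rs$len[(hi + 1L):n] else numeric(0)
  tail_isa <- if (hi < n) rs$isa[(hi + 1L):n] else logical(0)
  rs$len <- c(head_len, newlen, tail_len)
  rs$isa <- c(head_isa, newisa, tail_isa)
  for (j in seq_along(newlen)) {
    if (newisa[j]) rs$hA <- .hist_add(rs$hA, newlen[j], +1)
    else rs$hB <- .hist_add(rs$hB, newlen[j], +1)
  }
  # guard: adjacent same-type runs can arise when a run shrinks to length 0
  rs
}

.circ <- function(i, n) ((i - 1L) %% n) + 1L

# pick a run uniformly among those of the given type with length in
# [Lmin, Lmax] (histogram-counted, then located in one pass)
.pick_run <- function(rs, wantA, Lmin, Lmax = Lmin) {
  h <- if (wantA) rs$hA else rs$hB
  hi <- min(length(h), Lmax)
  if (Lmin > hi) return(NA_integer_)
  cnt <- sum(h[Lmin:hi])
  if (cnt < 1) return(NA_integer_)
  k <- sample.int(cnt, 1L)
  i <- cpp_find_kth_run(rs$len, rs$isa, wantA, Lmin, hi, k)
  if (i < 0) NA_integer_ else i
}

# in-place single-run length update (the common case; avoids rebuilding)
.set_len <- function(rs, i, newlen) {
  old <- rs$len[i]
  if (rs$isa[i]) {
    rs$hA <- .hist_add(rs$hA, old, -1)
    rs$hA <- .hist_add(rs$hA, newlen, +1)
  } else {
    rs$hB <- .hist_add(rs$hB, old, -1)
    rs$hB <- .hist_add(rs$hB, newlen, +1)
  }
  rs$len[i] <- newlen
  rs
}

# per-process total event rates for the current state
.oracle_totals <- function(rs, subst, eps, kap, iota) {
  hA <- rs$hA; hB <- rs$hB
  if (length(hA) > length(eps) &&
      any(hA[(length(eps) + 1L):length(hA)] > 0))
    stop("oracle-invalid: a tract outgrew the rate table", call. = FALSE)
  LA <- seq_along(hA); LB <- seq_along(hB)
  sA <- hA > 0; sB <- hB > 0
  A1 <- if (length(hA)) hA[1L] else 0
  B1 <- if (length(hB)) hB[1L] else 0
  nB <- sum(hB); B2 <- nB - B1
  c(lengthen = subst$lengthen * 2 * B2,
    shorten = subst$shorten * 2 * (sum(hA) - A1),
    fission = subst$fission * sum(pmax(LA - 2, 0)[sA] * hA[sA]),
    fusion = subst$fusion * B1,
    create = subst$create_a1 * sum(pmax(LB - 2, 0)[sB] * hB[sB]),
    destroy = subst$destroy_a1 * A1,
    expansion = sum(eps[LA][sA] * LA[sA] * hA[sA]),
    contraction = sum(kap[LA][sA] * LA[sA] * hA[sA] * (LA[sA] >= 2)),
    insertion = sum(iota[LA][sA] * pmax(LA - 1, 0)[sA] * hA[sA]),
    b_insert = subst$b_insert * sum(pmax(LB - 1, 0)[sB] * hB[sB]),
    b_delete = subst$b_delete * sum(pmax(LB - 2, 0)[sB] * hB[sB]),
    b1_delete = subst$b1_delete * B1)
}

# sample a populated A-length with weights w[L], then one run of that length
.pick_a_by_weight <- function(rs, w) {
  w[is.na(w) | w < 0] <- 0
  L <- sample.int(length(w), 1L, prob = w)
  list(i = .pick_run(rs, TRUE, L), L = L)
}

.pick_b_by_weight <- function(rs, w) {
  w[is.na(w) | w < 0] <- 0
  K <- sample.int(length(w), 1L, prob = w)
  list(i = .pick_run(rs, FALSE, K), K = K)
}

.apply_oracle_event <- function(rs, type, subst, eps, kap, iota) {
  n <- length(rs$len)
  hA <- rs$hA; hB <- rs$hB
  LA <- seq_along(hA); LB <- seq_along(hB)
  if (type == "lengthen") {
    i <- .pick_run(rs, FALSE, 2, Inf)
    if (is.na(i)) return(rs)
    side <- sample(c(-1L, 1L), 1L)
    j <- .circ(i + side, n)
    rs <- .set_len(rs, i, rs$len[i] - 1)
    rs <- .set_len(rs, j, rs$len[j] + 1)
  } else if (type == "shorten") {
    i <- .pick_run(rs, TRUE, 2, Inf)
    if (is.na(i)) return(rs)
    side <- sample(c(-1L, 1L), 1L)
    j <- .circ(i + side, n)
    rs <- .set_len(rs, i, rs$len[i] - 1)
    rs <- .set_len(rs, j, rs$len[j] + 1)
  } else if (type == "fission") {
    pk <- .pick_a_by_weight(rs, pmax(LA - 2, 0) * hA)
    if (is.na(pk$i)) return(rs)
    L <- pk$L
    p <- sample.int(L - 2L, 1L) + 1L # interior unit position 2..L-1
    rs <- .replace_block(rs, pk$i, c(p - 1, 1, L - p), c(TRUE, FALSE, TRUE))
  } else if (type == "fusion") {
    i <- .pick_run(rs, FALSE, 1)
    if (is.na(i) || n < 3L) return(rs)
    lft <- .circ(i - 1L, n); rgt <- .circ(i + 1L, n)
    if (lft == rgt) return(rs)
    rs <- .replace_block(rs, sort(c(lft, i, rgt)),
                         rs$len[lft] + rs$len[rgt] + 1, TRUE)
  } else if (type == "create") {
    pk <- .pick_b_by_weight(rs, pmax(LB - 2, 0) * hB)
    if (is.na(pk$i)) return(rs)
    K <- pk$K
    p <- sample.int(K - 2L, 1L) + 1L
    rs <- .replace_block(rs, pk$i, c(p - 1, 1, K - p), c(FALSE, TRUE, FALSE))
  } else if (type == "destroy") {
    i <- .pick_run(rs, TRUE, 1)
    if (is.na(i) || n < 3L) return(rs)
    lft <- .circ(i - 1L, n); rgt <- .circ(i + 1L, n)
    if (lft == rgt) return(rs)
    rs <- .replace_block(rs, sort(c(lft, i, rgt)),
                         rs$len[lft] + rs$len[rgt] + 1, FALSE)
  } else if (type == "expansion") {
    pk <- .pick_a_by_weight(rs, eps[LA] * LA * hA)
    if (is.na(pk$i)) return(rs)
    rs <- .set_len(rs, pk$i, pk$L + 1)
  } else if (type == "contraction") {
    w <- kap[LA] * LA * hA
    w[1L] <- 0
    pk <- .pick_a_by_weight(rs, w)
    if (is.na(pk$i)) return(rs)
    rs <- .set_len(rs, pk$i, pk$L - 1)
  } else if (type == "insertion") {
    pk <- .pick_a_by_weight(rs, iota[LA] * pmax(LA - 1, 0) * hA)
    if (is.na(pk$i)) return(rs)
    L <- pk$L
    j <- sample.int(L - 1L, 1L) # internal junction
    rs <- .replace_block(rs, pk$i, c(j, 1, L - j), c(TRUE, FALSE, TRUE))
  } else if (type == "b_insert") {
    pk <- .pick_b_by_weight(rs, pmax(LB - 1, 0) * hB)
    if (is.na(pk$i)) return(rs)
    rs <- .set_len(rs, pk$i, pk$K + 1)
  } else if (type == "b_delete") {
    pk <- .pick_b_by_weight(rs, pmax(LB - 2, 0) * hB)
    if (is.na(pk$i)) return(rs)
    rs <- .set_len(rs, pk$i, pk$K - 1)
  } else if (type == "b1_delete") {
    i <- .pick_run(rs, FALSE, 1)
    if (is.na(i) || n < 3L) return(rs)
    lft <- .circ(i - 1L, n); rgt <- .circ(i + 1L, n)
    if (lft == rgt) return(rs)
    rs <- .replace_block(rs, sort(c(lft, i, rgt)),
                         rs$len[lft] + rs$len[rgt], TRUE)
  }
  rs
}

# one replicate of the sequence-level simulation on a run-length state
simulate_runs <- function(rs, subst, curve, generations) {
  eps <- curve$eps; kap <- curve$kap; iota <- curve$iota
  types <- c("lengthen", "shorten", "fission", "fusion", "create", "destroy",
             "expansion", "contraction", "insertion",
             "b_insert", "b_delete", "b1_delete")
  # single-event validity: no per-run event probability may approach 1
  check_valid <- function(rs) {
    LA <- seq_along(rs$hA)
    sA <- rs$hA > 0
    if (!any(sA)) return()
    Lmax <- max(LA[sA])
    if (Lmax > length(eps))
      stop("oracle-invalid: tract length ", Lmax,
           " exceeds the rate table", call. = FALSE)
    pmax_run <- max(eps[1:Lmax] * (1:Lmax), kap[1:Lmax] * (1:Lmax),
                    iota[1:Lmax] * pmax(0:(Lmax - 1), 0),
                    subst$fission * pmax((1:Lmax) - 2, 0),
                    2 * subst$lengthen, 2 * subst$shorten)
    if (pmax_run >= 0.5)
      stop("oracle-invalid: per-tract event probability ",
           signif(pmax_run, 3), " >= 0.5", call. = FALSE)
  }
  check_valid(rs)
  for (g in seq_len(generations)) {
    lam <- .oracle_totals(rs, subst, eps, kap, iota)
    nev <- stats::rpois(1L, sum(lam))
    if (nev == 0L) next
    for (e in seq_len(nev)) {
      if (e > 1L) lam <- .oracle_totals(rs, subst, eps, kap, iota)
      type <- sample(types, 1L, prob = pmax(lam, 0))
      rs <- .apply_oracle_event(rs, type, subst, eps, kap, iota)
    }
    if (g %% 200L == 0L) check_valid(rs)
  }
  rs
}

#' Sequence-level forward simulator (brute-force oracle)
#'
#' Applies the mutational processes of the binned kernel literally to an
#' explicit sequence (internally a circular run-length representation of the
#' binary A / non-A genome): substitutions are drawn at their trinucleotide
#' context targets, expansions/contractions at per-target rate x L,
#' non-motif insertions at per-target rate x (L-1) with uniform interior
#' placement, and fission/fusion emerge from the sequence itself with no bin
#' bookkeeping.  Serves as the independent oracle for [kernel_step()].
#'
#' @param sequence Character string; sites equal to `a_char` are repeat
#'   units, everything else is non-repeat.
#' @param subst A [substitution_rates()].
#' @param curve A [rate_curve()] long enough to cover any tract the
#'   simulation can reach.
#' @param generations Number of generations.
#' @param seed Integer seed.
#' @param a_char The repeat unit character.
#' @param return_state If `TRUE`, return the run-length state (with tract
#'   and B-string histograms `hA`, `hB`) instead of the sequence string.
#' @return The evolved sequence (or state).
#' @export
sequence_level_simulate <- function(sequence, subst, curve, generations,
                                    seed = 1L, a_char = "A",
                                    return_state = FALSE) {
  withr_seed(seed)
  rs <- runs_from_sequence(sequence, a_char = a_char)
  rs <- simulate_runs(rs, subst, curve, generations)
  if (return_state) return(rs)
  chars <- ifelse(rs$isa, a_char, "C")
  paste(rep(chars, times = rs$len), collapse = "")
}

#' Synthetic primate-like DRL ensemble
#'
#' Draws `n` replicate DRLs around a base DRL with gamma-Poisson per-bin
#' noise (multiplier ~ Gamma(shape = dispersion, rate = dispersion), so
#' larger `dispersion` means a tighter ensemble; per-bin coefficient of
#' variation is about `1/sqrt(dispersion)` plus counting noise), then
#' applies the low-count truncation rule.  Emulates the assembly-quality and
#' stochastic variation of a set of related genomes.
#'
#' @param base A [drl()] (an equilibrated model DRL at genome scale).
#' @param n Ensemble size.
#' @param dispersion Gamma shape parameter (default 100, i.e. ~10% per-bin
#'   variation).
#' @param seed Integer seed.
#' @param truncate_threshold Count threshold for [truncate_low_counts()]
#'   (`NULL` to skip).
#' @return A list of [drl()] objects.
#' @export
generate_primate_ensemble <- function(base, n = 36L, dispersion = 100,
                                      seed = 1L, truncate_threshold = 30) {
  stopifnot(inherits(base, "drl"), n >= 1L, dispersion > 0)
  withr_seed(seed)
  lapply(seq_len(n), function(i) {
    g <- stats::rgamma(length(base$counts), shape = dispersion,
                       rate = dispersion)
    cts <- stats::rpois(length(base$counts), base$counts * g)
    d <- drl(cts, motif = base$motif,
             source = sprintf("synthetic ensemble member %d", i))
    if (!is.null(truncate_threshold)) truncate_low_counts(d, truncate_threshold)
    else d
  })
}
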