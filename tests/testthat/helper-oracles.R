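# Independent brute-force references used by the tests.  These are written
# as plain loops so that they share no code with the package's vectorized
# scanners.

# all maximal period-k repeated regions of a string: naive O(n^2) extension
brute_regions <- function(s, k) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  ok <- ch %in% c("A", "C", "G", "T")
  out <- list()
  i <- 1L
  while (i + k <= n) {
    if (ok[i] && ok[i + k] && ch[i] == ch[i + k]) {
      j <- i
      while (j + k <= n && ok[j] && ok[j + k] && ch[j] == ch[j + k]) j <- j + 1L
      # region covers i .. j-1+k; needs at least two complete units
      if (j - i >= k)
        out[[length(out) + 1L]] <- c(start = i, end = j - 1L + k)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# brute-force class DRL (mirrors the documented counting semantics)
brute_extract <- function(s, k, reverse_complement = TRUE) {
  s <- toupper(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  ok <- ch %in% c("A", "C", "G", "T")
  lab_of <- function(m) {
    if (!is_prim(m)) return(NA_character_)
    rots <- vapply(seq_len(nchar(m)) - 1L, function(d)
      paste0(substr(m, d + 1L, nchar(m)), substr(m, 1L, d)), character(1))
    if (reverse_complement) {
      rc <- chartr("ACGT", "TGCA",
                   paste(rev(strsplit(m, "", fixed = TRUE)[[1L]]), collapse = ""))
      rots <- c(rots, vapply(seq_len(nchar(rc)) - 1L, function(d)
        paste0(substr(rc, d + 1L, nchar(rc)), substr(rc, 1L, d)), character(1)))
    }
    min(rots)
  }
  is_prim <- function(m) {
    kk <- nchar(m)
    for (d in seq_len(kk - 1L)) {
      if (kk %% d == 0L && strrep(substr(m, 1L, d), kk / d) == m) return(FALSE)
    }
    TRUE
  }
  tal <- list()
  bump <- function(lab, L) {
    key <- lab
    cur <- tal[[key]]
    if (is.null(cur)) cur <- numeric(0)
    if (L > length(cur)) cur <- c(cur, numeric(L - length(cur)))
    cur[L] <- cur[L] + 1
    tal[[key]] <<- cur
  }
  regions <- brute_regions(s, k)
  covered <- rep(FALSE, n)
  for (rg in regions) {
    span <- rg[["end"]] - rg[["start"]] + 1L
    unit <- substr(s, rg[["start"]], rg[["start"]] + k - 1L)
    lab <- lab_of(unit)
    if (is.na(lab)) next
    covered[rg[["start"]]:rg[["end"]]] <- TRUE
    bump(lab, span %/% k)
  }
  # single units: window valid, primitive, not extendable in phase either
  # way, not fully inside a counted region
  for (p in seq_len(max(0L, n - k + 1L))) {
    win <- substr(s, p, p + k - 1L)
    if (!all(ok[p:(p + k - 1L)])) next
    lab <- lab_of(win)
    if (is.na(lab)) next
    fwd <- p + 2L * k - 1L <= n && substr(s, p + k, p + 2L * k - 1L) == win &&
      all(ok[(p + k):(p + 2L * k - 1L)])
    bwd <- p - k >= 1L && substr(s, p - k, p - 1L) == win &&
      all(ok[(p - k):(p - 1L)])
    if (fwd || bwd) next
    if (all(covered[p:(p + k - 1L)])) next
    bump(lab, 1L)
  }
  tal
}

# standard small rate setup shared by dynamics tests
toy_curve <- function(Lb = 40, e0 = 2e-6, k0 = 1.5e-6, i0 = 2e-7) {
  L <- seq_len(Lb)
  rate_curve(eps = e0 * L, kap = c(0, k0 * (2:Lb)^1.2), iota = rep(i0, Lb))
}

toy_state <- function(G = 1e6, subst = substitution_rates(), Lb = 40) {
  initialize_state(G, subst, L_bound = Lb, L_bound_b = Lb, pre_run = FALSE)
}

total_length <- function(st) {
  sum(seq_along(st$a) * st$a) + sum(seq_along(st$b) * st$b)
}
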