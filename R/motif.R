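#' Motif equivalence classes
#'
#' Simple tandem repeat motifs are pooled into equivalence classes formed by
#' all cyclic permutations of a motif together with the cyclic permutations of
#' its reverse complement; outside of specific biological hypotheses
#' (transcription direction, protein binding) these are bioinformatically and
#' biologically indistinguishable.  The class label is the alphabetically
#' smallest member, so e.g. both CAG and CTG repeats belong to class "AGC".
#'
#' @param motif A motif string over A/C/G/T, length 1-6, primitive (not a
#'   whole-number repetition of a shorter motif).
#' @return An object of class `motif_class`: a list with `label` (canonical
#'   motif), `unit_length`, and `members` (all member motif strings).
#' @examples
#' canonical_label("CTG")$label   # "AGC"
#' canonical_label("A")$members   # "A" and "T"
#' @export
canonical_label <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif) || !nzchar(motif))
    stop("`motif` must be a single non-empty string", call. = FALSE)
  motif <- toupper(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("invalid alphabet: motif must contain only A, C, G, T", call. = FALSE)
  k <- length(chars)
  if (k > 6L)
    stop("motif unit length must be between 1 and 6", call. = FALSE)
  if (!is_primitive_motif(motif))
    stop("degenerate motif: '", motif,
         "' is a repetition of a shorter motif", call. = FALSE)
  members <- sort(unique(c(rotations(motif), rotations(revcomp(motif)))))
  structure(list(label = members[[1L]], unit_length = k, members = members),
            class = "motif_class")
}

#' @export
print.motif_class <- function(x, ...) {
  cat("<motif_class> ", x$label, " (unit ", x$unit_length, " nt; members: ",
      paste(x$members, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

rotations <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(m)
  d <- paste0(m, m)
  vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), character(1))
}

revcomp <- function(m) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(m, "", fixed = TRUE)[[1L]]), collapse = ""))
}

is_primitive_motif <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (strrep(substr(m, 1L, d), k / d) == m) return(FALSE)
  }
  TRUE
}

#' All primitive motif classes of a given unit length
#'
#' @param unit_length Motif unit length in nt (1-6).
#' @return A list of `motif_class` objects, one per equivalence class.
#' @export
motif_classes_of_length <- function(unit_length) {
  stopifnot(unit_length >= 1L, unit_length <= 6L)
  alph <- c("A", "C", "G", "T")
  grids <- do.call(expand.grid,
                   c(rep(list(alph), unit_length),
                     list(stringsAsFactors = FALSE)))
  motifs <- do.call(paste0, grids)
  motifs <- motifs[vapply(motifs, is_primitive_motif, logical(1))]
  labels <- vapply(motifs, function(m) {
    min(c(rotations(m), rotations(revcomp(m))))
  }, character(1))
  lapply(unique(labels)[order(unique(labels))], canonical_label)
}
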