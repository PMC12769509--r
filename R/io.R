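#' Read a FASTA file
#'
#' Reads a (multi-record) FASTA file; records are kept separate (tracts are
#' never formed across records) and soft-masked lowercase bases are
#' uppercased.  Uses Biostrings when available, otherwise a plain-text
#' fallback reader.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("malformed FASTA: no header lines in ", path, call. = FALSE)
  grp <- cumsum(hdr)
  nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(v) toupper(paste(v, collapse = "")), character(1))
  names(seqs) <- nm
  seqs
}

#' Write sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read DRL tables
#'
#' TSV with columns `motif_label`, `unit_length`, `tract_length_units`,
#' `count` (plus `prob` for normalized DRLs, whose `L_min` is recorded in a
#' `#` metadata header).  Round trips losslessly.
#'
#' @param drls A [drl()], `normalized_drl`, or a (named) list of them.
#' @param path File path.
#' @export
write_drl_table <- function(drls, path) {
  if (inherits(drls, "drl") || inherits(drls, "normalized_drl"))
    drls <- list(drls)
  meta <- character()
  rows <- lapply(drls, function(d) {
    if (inherits(d, "normalized_drl")) {
      nz <- which(d$probs > 0)
      meta <<- unique(c(meta, paste0("L_min=", d$L_min),
                        paste0("total=", format(d$total, digits = 17))))
      data.frame(motif_label = d$motif$label,
                 unit_length = d$motif$unit_length,
                 tract_length_units = nz,
                 count = d$probs[nz] * d$total,
                 prob = d$probs[nz])
    } else {
      nz <- which(d$counts > 0)
      data.frame(motif_label = d$motif$label,
                 unit_length = d$motif$unit_length,
                 tract_length_units = nz,
                 count = d$counts[nz])
    }
  })
  .write_tsv(do.call(rbind, rows), path, meta = meta)
}

#' @rdname write_drl_table
#' @param mapping Named character vector renaming nonstandard columns,
#'   e.g. `c(motif_label = "motif", tract_length_units = "length")`.
#' @return `read_drl_table()`: a named list of [drl()] objects.
#' @export
read_drl_table <- function(path, mapping = NULL) {
  tab <- .read_tsv(path)
  if (!is.null(mapping))
    for (std in names(mapping)) {
      if (!mapping[[std]] %in% names(tab))
        stop("mapping error: no column '", mapping[[std]], "' in ", path,
             call. = FALSE)
      names(tab)[names(tab) == mapping[[std]]] <- std
    }
  need <- c("motif_label", "tract_length_units", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("mapping error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(tab, tab$motif_label), function(g) {
    cts <- numeric(max(g$tract_length_units))
    cts[g$tract_length_units] <- g$count
    drl(cts, motif = g$motif_label[1L], source = path)
  })
  out
}

#' Write / read instability rate tables
#'
#' TSV with columns `process` (expansion | contraction |
#' non_motif_insertion), `tract_length_units`,
#' `rate_per_target_per_generation`, optional `ci_lo`, `ci_hi`, and
#' `provenance`.  Every length from 1 to the table maximum must be present
#' for each process; gaps raise an error rather than becoming silent zeros.
#'
#' @param curve A [rate_curve()].
#' @param path File path.
#' @export
write_rate_table <- function(curve, path) {
  L <- seq_along(curve$eps)
  df <- rbind(
    data.frame(process = "expansion", tract_length_units = L,
               rate_per_target_per_generation = curve$eps,
               provenance = curve$provenance),
    data.frame(process = "contraction", tract_length_units = L,
               rate_per_target_per_generation = curve$kap,
               provenance = curve$provenance),
    data.frame(process = "non_motif_insertion", tract_length_units = L,
               rate_per_target_per_generation = curve$iota,
               provenance = curve$provenance))
  .write_tsv(df, path)
}

#' @rdname write_rate_table
#' @param mapping Optional named character vector renaming nonstandard
#'   columns to the standard names.
#' @return `read_rate_table()`: a [rate_curve()].
#' @export
read_rate_table <- function(path, mapping = NULL) {
  tab <- .read_tsv(path)
  if (!is.null(mapping))
    for (std in names(mapping)) {
      if (!mapping[[std]] %in% names(tab))
        stop("mapping error: no column '", mapping[[std]], "' in ", path,
             call. = FALSE)
      names(tab)[names(tab) == mapping[[std]]] <- std
    }
  need <- c("process", "tract_length_units", "rate_per_target_per_generation")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("mapping error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  Lmax <- max(tab$tract_length_units)
  get <- function(p) {
    g <- tab[tab$process == p, ]
    g <- g[order(g$tract_length_units), ]
    if (!identical(as.integer(g$tract_length_units), seq_len(Lmax)))
      stop("gap error: process '", p, "' is missing length rows", call. = FALSE)
    g$rate_per_target_per_generation
  }
  prov <- tab$provenance[tab$process == "expansion"]
  if (is.null(prov)) prov <- rep("parameterized", Lmax)
  rate_curve(get("expansion"), get("contraction"),
             get("non_motif_insertion"),
             provenance = prov[order(tab$tract_length_units[tab$process == "expansion"])])
}

#' Write / read substitution rates as YAML
#' @param subst A [substitution_rates()].
#' @param path File path.
#' @export
write_subst_yaml <- function(subst, path) {
  yaml::write_yaml(unclass(subst)[c("lengthen", "shorten", "fission",
                                    "fusion", "create_a1", "destroy_a1",
                                    "b_insert", "b_delete", "b1_delete")],
                   path)
  invisible(path)
}

#' @rdname write_subst_yaml
#' @return `read_subst_yaml()`: a [substitution_rates()].
#' @export
read_subst_yaml <- function(path) {
  do.call(substitution_rates, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Convenience driver tying the stages together: generate (or load) a
#' genome, extract its mono-A DRL, evolve a truth model, build a synthetic
#' ensemble, run grid ABC, and report posterior summaries plus steady-state
#' diagnostics as a JSON-ready list.  All seeds and grid definitions are
#' recorded in the report.
#'
#' @param config A list; see the worked example in the package README.
#'   Recognized entries: `seed`, `genome_length`, `family`, `grid`
#'   (data frame), `truth` (named parameter vector), `ensemble_n`,
#'   `dispersion`, `sim` (a [sim_config()]), `cfg` (an
#'   [inference_config()]), `out_dir` (optional: persist intermediates).
#' @return The report list (invisibly written to
#'   `file.path(out_dir, "report.json")` when `out_dir` is given).
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  fam <- config$family %||% "multiplier_coupled_power"
  sim <- config$sim %||% sim_config(
    schedule = data.frame(r = 3:0, iterations = 2e4), conv_tol = 1e-4)
  cfg <- config$cfg %||% inference_config()
  subst <- config$subst %||% substitution_rates()
  emp <- config$emp_rates %||% empirical_rates_mono_a()
  G <- config$genome_length %||% 3.1e9

  init <- initialize_state(G, subst)
  truth <- config$truth %||% c(m = 4, tau_eps = 1.6, tau_kap = 2.0)
  spec <- param_spec(fam, truth)
  curve <- build_rate_table(spec, emp, L_bound = sim$L_cap, subst = subst)
  truth_ev <- evolve(init, subst, curve, sim)
  truth_drl <- drl(truth_ev$state$a, motif = "A", source = "truth model")

  ens <- generate_primate_ensemble(truth_drl, n = config$ensemble_n %||% 36L,
                                   dispersion = config$dispersion %||% 100,
                                   seed = seed + 1L)
  sigma <- primate_sigma(ens, truth_drl, cfg)

  grid <- config$grid %||% expand.grid(m = c(2.5, 4, 6.4),
                                       tau_eps = seq(1.2, 2.0, 0.4),
                                       tau_kap = seq(1.6, 2.4, 0.4))
  pg <- infer_grid(fam, grid, truth_drl, prior = NULL, sigma = sigma,
                   cfg = cfg, init = init, subst = subst, emp_rates = emp,
                   sim = sim)
  best <- param_spec(fam, unlist(pg$max_posterior))
  diag <- classify_regime(best, truth_drl$counts, emp_rates = emp)

  report <- list(seed = seed, family = fam,
                 grid = list(n = nrow(grid), columns = names(grid)),
                 sigma = sigma,
                 truth = as.list(truth),
                 max_posterior = pg$max_posterior,
                 mean_posterior = as.list(pg$mean_posterior),
                 log_bayes_factor = pg$bf$log_bf,
                 delta_tau = diag$delta_tau,
                 regime = diag$regime,
                 L_star = diag$L_star,
                 L_trunc = diag$L_trunc,
                 equilibrated = truth_ev$equilibrated,
                 generations = truth_ev$generations)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_drl_table(truth_drl, file.path(config$out_dir, "truth_drl.tsv"))
    write_rate_table(curve, file.path(config$out_dir, "truth_rates.tsv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
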