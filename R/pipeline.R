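# End-to-end pipeline orchestration: factorize -> select rank ->
# logical resources -> surface-code compile -> report, with JSON
# artifacts, deterministic seeding, and config-hash provenance.

MODEL_VERSION <- "qrechem-cost-model-1"

#' Validate a pipeline configuration
#'
#' A configuration is a named list (typically read from JSON) with:
#' * `input`: path to an FCIDUMP file, or `synthesis`: list
#'   `(n_orb, cholesky_rank)` for an in-repo synthetic Hamiltonian
#'   (exactly one of the two);
#' * `schemes`: subset of `"SF"`, `"DF"`, `"THC"`;
#' * `threshold`: rank-selection error threshold in Hartree;
#' * `budget`: optional list of precision-budget shares;
#' * `hardware`: optional list of [hardware_assumptions()] fields;
#' * `grid`: optional surface-code search grid overrides;
#' * `seed`: integer (mandatory - no wall-clock randomness);
#' * `out_dir`: artifact directory.
#'
#' @param cfg Named list.
#' @return The validated (normalized) config.  Errors describe the
#'   offending field.
#' @export
validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a named list")
  has_input <- !is.null(cfg$input)
  has_synth <- !is.null(cfg$synthesis)
  if (has_input == has_synth)
    stop("config must have exactly one of 'input' (FCIDUMP path) or 'synthesis'")
  if (has_synth) {
    s <- cfg$synthesis
    if (is.null(s$n_orb) || is.null(s$cholesky_rank) ||
        s$n_orb < 1 || s$cholesky_rank < 1)
      stop("synthesis must give positive n_orb and cholesky_rank")
  }
  if (is.null(cfg$seed)) stop("config must carry an explicit integer seed")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$schemes)) cfg$schemes <- c("SF", "DF", "THC")
  bad <- setdiff(cfg$schemes, c("SF", "DF", "THC"))
  if (length(bad)) stop("unknown scheme(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$thc_rank) && !("THC" %in% cfg$schemes))
    stop("thc_rank given but THC is not among the schemes")
  if (is.null(cfg$threshold)) cfg$threshold <- 1e-3
  if (cfg$threshold <= 0) stop("threshold must be positive")
  cfg$budget <- do.call(precision_budget,
                        if (is.null(cfg$budget)) list() else cfg$budget)
  cfg$hardware <- do.call(hardware_assumptions,
                          if (is.null(cfg$hardware)) list() else cfg$hardware)
  if (is.null(cfg$grid)) cfg$grid <- default_grid_spec()
  if (is.null(cfg$out_dir)) stop("config must give out_dir")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_artifact <- function(obj, path, provenance) {
  obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  path
}

#' Run the full resource-estimation pipeline
#'
#' Executes, per requested scheme: factorization of the input
#' Hamiltonian, accuracy-controlled rank selection, lambda and logical
#' resource estimation, and surface-code compilation; writes one JSON
#' artifact per stage plus a human-readable summary table, every file
#' embedding the config hash, seed, and cost-model version.  Any stage
#' error aborts with the stage name attached.
#'
#' @param cfg A config list (see [validate_pipeline_config()]).
#' @return Invisibly, a list with the summary data frame and artifact
#'   paths.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
               seed = cfg$seed,
               model_version = MODEL_VERSION)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name) {
    message(sprintf("[qrechem] %-12s t+%.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }

  log_stage("input")
  h <- stage("input", {
    if (!is.null(cfg$input)) read_fcidump(cfg$input)
    else synthesize_hamiltonian(cfg$synthesis$n_orb,
                                cfg$synthesis$cholesky_rank, cfg$seed)
  })
  artifacts <- character(0)
  rows <- list()
  for (scheme in cfg$schemes) {
    log_stage(paste0("select:", scheme))
    sel <- stage(paste0("select_rank:", scheme),
                 select_rank(h, scheme, threshold = cfg$threshold,
                             seed = cfg$seed))
    f <- stage(paste0("factorize:", scheme), switch(scheme,
      SF = single_factorize(h, n_vectors = sel$selected_knob),
      DF = double_factorize(single_factorize(h, tol = 0),
                            leaf_tol = sel$selected_knob),
      THC = thc_factorize(h, rank = sel$selected_knob, seed = cfg$seed)))
    log_stage(paste0("logical:", scheme))
    res <- stage(paste0("resources:", scheme),
                 estimate_resources(h, f, cfg$budget))
    log_stage(paste0("compile:", scheme))
    phys <- stage(paste0("compile:", scheme),
                  optimize_config(cfg$hardware, res$logical_qubits,
                                  res$toffoli_total, cfg$grid))
    pfx <- file.path(cfg$out_dir, tolower(scheme))
    artifacts <- c(artifacts,
      write_artifact(list(stage = "selection", scheme = scheme,
                          threshold = cfg$threshold,
                          selected = sel$selected_knob,
                          error_at_selection = sel$error_at_selection,
                          trace = sel$trace),
                     paste0(pfx, "_selection.json"), prov),
      write_artifact(list(stage = "factorization",
                          payload = serialize_factorization(f)),
                     paste0(pfx, "_factorization.json"), prov),
      write_artifact(list(stage = "logical_resources",
                          resources = unclass_deep(res)),
                     paste0(pfx, "_resources.json"), prov),
      write_artifact(list(stage = "physical_estimate",
                          estimate = unclass_deep(phys)),
                     paste0(pfx, "_physical.json"), prov))
    rows[[scheme]] <- data.frame(
      method = scheme, rank_knob = sel$selected_knob,
      lambda = res$lambda_val, toffolis = res$toffoli_total,
      logical_qubits = res$logical_qubits,
      physical_qubits = phys$physical_qubits,
      runtime_hours = phys$runtime_hours,
      success_probability = 1 - phys$p_fail_total)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  spath <- file.path(cfg$out_dir, "summary.json")
  write_artifact(list(stage = "summary", table = summary), spath, prov)
  tpath <- file.path(cfg$out_dir, "summary.txt")
  writeLines(c(sprintf("qrechem pipeline summary (seed %d, config %s)",
                       cfg$seed, prov$config_hash),
               utils::capture.output(print(summary, row.names = FALSE))),
             tpath)
  log_stage("done")
  invisible(list(summary = summary, artifacts = c(artifacts, spath, tpath),
                 provenance = prov))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Serialize a factorization to a versioned list (JSON container)
#'
#' Layout version `qrechem-fact-1`: `method`, `rank` parameters, and the
#' numeric payloads (`vectors` / `eigenvalues` + `eigenvectors` /
#' `chi` + `zeta`).
#'
#' @param f A factorization object.
#' @return A plain list suitable for `jsonlite::write_json()`.
#' @export
serialize_factorization <- function(f) {
  if (inherits(f, "sf_factorization"))
    list(layout = "qrechem-fact-1", method = "SF", n_orb = f$n_orb,
         rank = f$n_vectors, vectors = f$vectors)
  else if (inherits(f, "df_factorization"))
    list(layout = "qrechem-fact-1", method = "DF", n_orb = f$n_orb,
         leaf_ranks = f$leaf_ranks, avg_rank = f$avg_rank,
         eigenvalues = lapply(f$leaves, `[[`, "f"),
         eigenvectors = lapply(f$leaves, `[[`, "U"))
  else if (inherits(f, "thc_factorization"))
    list(layout = "qrechem-fact-1", method = "THC", n_orb = f$n_orb,
         rank = f$rank, seed = f$seed, reg_strength = f$reg_strength,
         chi = f$chi, zeta = f$zeta)
  else stop("unknown factorization type")
}
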