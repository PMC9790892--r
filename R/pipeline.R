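# Case orchestration: run all nine (measured output x substitute kinetics)
# cases through the geometric and indistinguishable-dynamics stages, verify
# numerically, and emit the four summary tables.

#' The nine analysis cases
#'
#' The full Cartesian product of measured outputs and substitute kinetics
#' forms, in the canonical order of the analysis: oxygen-form substitutes
#' first (outputs nu3, nu1, nu2), then substrate-form (nu3, nu1, nu2), then
#' the product form (nu1, nu2, nu3).
#'
#' @return Data frame with columns `case`, `output_index`, `form`.
#' @export
enumerate_cases <- function() {
  data.frame(
    case = 1:9,
    output_index = c(3L, 1L, 2L, 3L, 1L, 2L, 1L, 2L, 3L),
    form = c("O", "O", "O", "S", "S", "S", "SO", "SO", "SO"),
    stringsAsFactors = FALSE
  )
}

#' Affine model for one analysis case
#'
#' Builds the case's substitute kinetics by mean parameterisation of the true
#' kinetics bounds and assembles the affine model with the case's measured
#' output.
#'
#' @param case_row One row of [enumerate_cases()] (or any list with
#'   `output_index` and `form`).
#' @param params A `cstr_parameters` object.
#' @param true_kin A `true_kinetics` object supplying the parameter bounds.
#' @return An `affine_model`.
#' @export
case_model <- function(case_row, params = cstr_parameters(),
                       true_kin = true_kinetics()) {
  sub <- mean_parameterize(true_kin, form = case_row$form)
  build_affine_model(params, sub, case_row$output_index)
}

subcases_for <- function(output_index) {
  if (output_index == 1L) c("generic", "washout-ic", "washout-asymptotic")
  else "generic"
}

yn <- function(x) ifelse(is.na(x), "-", ifelse(x, "Yes", "No"))

#' Analysis configuration
#'
#' @param cases Subset of case ids (1..9) to analyse.
#' @param seeds Integer seeds for verification scenarios.
#' @param horizon Scenario horizon `c(t0, tf)`, h.
#' @param tol Detectability tolerance, g/L.
#' @param obs_tol Observability (numerical-zero) tolerance, g/L.
#' @param n_rank_points Points for observability-rank sampling.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param with_uncertainty,without_uncertainty Toggle the two
#'   indistinguishable-dynamics settings.
#' @param verify Run the paired-simulation verification stage.
#' @param params A `cstr_parameters` object.
#' @param true_kin A `true_kinetics` object (bounds define the substitute
#'   constants by mean parameterisation).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(cases = 1:9, seeds = 1:3, horizon = c(0, 50),
                            tol = 1e-5, obs_tol = 1e-7, n_rank_points = 200,
                            out_dir = NULL, with_uncertainty = TRUE,
                            without_uncertainty = TRUE, verify = TRUE,
                            params = cstr_parameters(),
                            true_kin = true_kinetics()) {
  if (!all(cases %in% 1:9)) stop("case ids must be in 1..9", call. = FALSE)
  if (tol <= 0 || obs_tol <= 0) stop("tolerances must be > 0", call. = FALSE)
  structure(list(cases = cases, seeds = as.integer(seeds), horizon = horizon,
                 tol = tol, obs_tol = obs_tol,
                 n_rank_points = n_rank_points, out_dir = out_dir,
                 with_uncertainty = with_uncertainty,
                 without_uncertainty = without_uncertainty, verify = verify,
                 params = params, true_kin = true_kin),
            class = "analysis_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; a `params` section sets
#' the CSTR constants and a `true_kinetics` section sets the kinetics bounds
#' (`mu_max`, `Ks`, `Ko` intervals). Missing keys keep their defaults.
#'
#' @param path Path to the YAML configuration.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- if (is.null(cfg$params)) cstr_parameters()
            else do.call(cstr_parameters, cfg$params)
  tk <- cfg$true_kinetics
  true_kin <- if (is.null(tk)) true_kinetics()
              else true_kinetics(mu_max = as.numeric(tk$mu_max),
                                 Ks = as.numeric(tk$Ks),
                                 Ko = as.numeric(tk$Ko))
  keep <- intersect(names(cfg),
                    c("cases", "seeds", "horizon", "tol", "obs_tol",
                      "n_rank_points", "out_dir", "with_uncertainty",
                      "without_uncertainty", "verify"))
  do.call(analysis_config,
          c(cfg[keep], list(params = params, true_kin = true_kin)))
}

classification_rows <- function(case_row, red, subcases) {
  do.call(rbind, lapply(subcases, function(sc) {
    cl <- classify_states(red, sc)
    wide <- c(stats::setNames(as.list(yn(cl$observable)),
                              paste0("obs_", cl$entity)),
              stats::setNames(as.list(yn(cl$detectable)),
                              paste0("det_", cl$entity)))
    cbind(data.frame(case = case_row$case,
                     output = paste0("nu", case_row$output_index),
                     form = case_row$form, subcase = sc,
                     stringsAsFactors = FALSE),
          as.data.frame(wide, stringsAsFactors = FALSE))
  }))
}

code_one <- function(label) {
  switch(label, measured = "M", observable = "O", detectable = "D",
         unobservable = "UO", `n/a` = "-")
}

consolidate_codes <- function(labels) {
  codes <- unique(vapply(labels, code_one, character(1)))
  order_ref <- c("M", "O", "D", "UO")
  paste(codes[order(match(codes, order_ref))], collapse = "/")
}

#' Run the full observability/detectability analysis
#'
#' For each selected case: builds the affine model, runs the geometric stage
#' (observability matrix, rank sampling, matching condition), both
#' indistinguishable-dynamics classifications (with and without the
#' unknown-input difference, including wash-out sub-cases for biomass
#' output), and, optionally, paired-simulation verification of every
#' observable/detectable label. Emits the four summary tables; when
#' `config$out_dir` is set, writes them as CSV plus a JSON report.
#'
#' @param config An `analysis_config`.
#' @return Object of class `analysis_summary` with elements `table1`
#'   (geometric verdicts), `table2` (with-uncertainty labels), `table3`
#'   (without-uncertainty labels), `table4` (consolidated M/O/UO/D coding),
#'   `verification` (per-label simulation checks) and `reports` (per-case
#'   geometric reports).
#' @export
run_all <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  cases <- enumerate_cases()
  cases <- cases[cases$case %in% config$cases, , drop = FALSE]

  t1 <- list(); t2 <- list(); t3 <- list(); ver <- list(); reports <- list()
  t4 <- list()
  for (i in seq_len(nrow(cases))) {
    cr <- cases[i, ]
    model <- case_model(cr, config$params, config$true_kin)
    rep_g <- observability_matrix(model, n_points = config$n_rank_points,
                                  seed = 1000L + cr$case)
    match_g <- matching_condition(model)
    reports[[as.character(cr$case)]] <- rep_g
    t1[[i]] <- data.frame(case = cr$case, output = paste0("nu", cr$output_index),
                          form = cr$form,
                          observable = yn(rep_g$verdict == "observable"),
                          matching = deparse1(match_g$value),
                          stringsAsFactors = FALSE)
    subcases <- subcases_for(cr$output_index)
    red_u <- red_n <- NULL
    if (config$with_uncertainty) {
      red_u <- reduce_for_output(build_error_system(model, TRUE), model)
      t2[[i]] <- classification_rows(cr, red_u, subcases)
    }
    if (config$without_uncertainty) {
      red_n <- reduce_for_output(build_error_system(model, FALSE), model)
      t3[[i]] <- classification_rows(cr, red_n, subcases)
    }

    # consolidated per-state coding
    geom_codes <- vapply(1:3, function(s) {
      if (s == cr$output_index) "M"
      else if (rep_g$verdict == "observable") "O" else "UO"
    }, character(1))
    state_codes <- function(red) {
      vapply(1:3, function(s) {
        labs <- vapply(subcases, function(sc)
          classify_states(red, sc)$label[s], character(1))
        consolidate_codes(labs)
      }, character(1))
    }
    t4[[i]] <- data.frame(
      case = cr$case,
      geom_nu1 = geom_codes[1], geom_nu2 = geom_codes[2],
      geom_nu3 = geom_codes[3],
      unc_nu1 = if (is.null(red_u)) NA else state_codes(red_u)[1],
      unc_nu2 = if (is.null(red_u)) NA else state_codes(red_u)[2],
      unc_nu3 = if (is.null(red_u)) NA else state_codes(red_u)[3],
      nounc_nu1 = if (is.null(red_n)) NA else state_codes(red_n)[1],
      nounc_nu2 = if (is.null(red_n)) NA else state_codes(red_n)[2],
      nounc_nu3 = if (is.null(red_n)) NA else state_codes(red_n)[3],
      stringsAsFactors = FALSE)

    if (config$verify) {
      for (seed in config$seeds) {
        for (setting in c(TRUE, FALSE)[c(config$with_uncertainty,
                                         config$without_uncertainty)]) {
          red <- if (setting) red_u else red_n
          sc <- generate_scenario(seed * 100L + cr$case,
                                  horizon = config$horizon)
          tf <- horizon_for_tolerance(sc, tol = config$tol)
          traj <- simulate_pair(sc, model, with_uncertainty = setting,
                                constrain_output = TRUE,
                                times = seq(sc$horizon[1], tf,
                                            length.out = 401))
          cl <- classify_states(red, "generic")
          vc <- verify_convergence(traj, cl, tol = config$tol,
                                   obs_tol = config$obs_tol)
          vc$case <- cr$case; vc$seed <- seed
          vc$with_uncertainty <- setting
          ver[[length(ver) + 1L]] <- vc
        }
      }
    }
  }
  out <- structure(list(
    table1 = do.call(rbind, t1),
    table2 = if (length(t2)) do.call(rbind, t2) else NULL,
    table3 = if (length(t3)) do.call(rbind, t3) else NULL,
    table4 = do.call(rbind, t4),
    verification = if (length(ver)) do.call(rbind, ver) else NULL,
    reports = reports,
    config = config
  ), class = "analysis_summary")
  if (!is.null(config$out_dir)) write_summary(out, config$out_dir)
  out
}

#' @export
print.analysis_summary <- function(x, ...) {
  cat("Observability/detectability analysis of", nrow(x$table1), "case(s)\n\n")
  cat("Geometric stage (sufficient rank condition):\n")
  print(x$table1, row.names = FALSE)
  if (!is.null(x$verification)) {
    bad <- x$verification[x$verification$status %in% c("fail", "inconclusive"), ]
    cat("\nVerification:", sum(x$verification$status == "pass"), "checks passed,",
        nrow(bad), "failed or inconclusive\n")
  }
  invisible(x)
}

#' Write the summary tables to disk
#'
#' Writes `table1.csv` ... `table4.csv` plus `report.json` (geometric
#' evidence and verification results in machine-readable form).
#'
#' @param summary An `analysis_summary`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("table1", "table2", "table3", "table4", "verification")) {
    if (!is.null(summary[[nm]]))
      utils::write.csv(summary[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  rep_json <- lapply(summary$reports, function(r) list(
    output_index = r$output_index, form = r$form,
    obs_map = vapply(r$obs_map, deparse1, character(1)),
    obs_matrix = lapply(r$obs_matrix, function(row)
      vapply(row, deparse1, character(1))),
    zero_columns = as.integer(r$zero_columns),
    sampled_ranks = as.list(r$sampled_ranks),
    verdict = r$verdict
  ))
  jsonlite::write_json(rep_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
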