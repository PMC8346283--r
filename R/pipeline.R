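#' Run the end-to-end gating-analysis pipeline
#'
#' Orchestrates the full study on a set of recordings or simulated
#' conditions: (optional) p/4 leak subtraction, steady-state extraction, G-V
#' conversion against the Nernst reversal potential, Boltzmann and
#' threshold fits per pH condition, assembly of the (delta_pH, V0.5, V_Thr)
#' table, and comparison against the allosteric-model prediction. Identical
#' config and seed give identical outputs.
#'
#' The configuration is a named list:
#' \describe{
#'   \item{inputs}{Optional list of trace-table paths (read with
#'     [read_current_family()]); or}
#'   \item{simulate}{Optional simulation block:
#'     \code{conditions} (list of \code{list(pH_o =, pH_i =)}),
#'     \code{gating} (an [allosteric_params()] or Boltzmann list),
#'     \code{g_max_nS}, \code{g_leak_nS}, \code{noise_sd_pA},
#'     \code{kinetics}, and optionally \code{protocol}. Without an explicit
#'     protocol, each condition gets a pulse grid centred on the
#'     model-predicted V0.5 (+/- 60 mV in 10 mV steps), as an experimenter
#'     would choose.}
#'   \item{model}{Optional [allosteric_params()] used for the prediction
#'     table and residuals (defaults to the simulation gating source when
#'     that is allosteric).}
#'   \item{v_thr_fraction}{Threshold fraction, default 0.1.}
#' }
#'
#' @param config Configuration list (above).
#' @param seed Integer seed used for all simulated noise.
#' @param verbose Log each stage to the console?
#' @return Object of class \code{"study_result"}: \code{fits} (per-condition
#'   fit records), \code{table} (delta_pH, V0.5, V_Thr with standard errors),
#'   \code{model_table}, \code{comparison} (residuals and RMS, when a model
#'   is available), \code{provenance} (seed, config hash, package version).
#' @export
run_pipeline <- function(config, seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(config$inputs) && is.null(config$simulate))
    stop("run_pipeline: config must name input files or a simulate block")
  v_thr_fraction <- if (is.null(config$v_thr_fraction)) 0.1 else config$v_thr_fraction

  families <- list()
  if (!is.null(config$inputs)) {
    if (length(config$inputs) == 0)
      stop("run_pipeline: empty input list")
    say("stage load: %d input tables", length(config$inputs))
    families <- lapply(config$inputs, read_current_family)
  } else {
    sim <- config$simulate
    if (is.null(sim$conditions) || length(sim$conditions) == 0)
      stop("run_pipeline: simulate block has no conditions")
    gating <- sim$gating
    say("stage simulate: %d pH conditions", length(sim$conditions))
    families <- lapply(seq_along(sim$conditions), function(i) {
      cond <- sim$conditions[[i]]
      protocol <- sim$protocol
      if (is.null(protocol)) {
        centre <- if (inherits(gating, "allosteric_params"))
          solve_v_half(gating, cond$pH_o, cond$pH_i) else gating$v_half
        grid <- round(centre / 10) * 10 + seq(-60, 60, by = 10)
        protocol <- voltage_protocol(holding_mV = min(grid) - 40,
                                     test_mV = grid,
                                     duration_ms = 400, dt_ms = 1)
      }
      generate_current_family(
        protocol, gating, cond$pH_o, cond$pH_i,
        kinetics = if (is.null(sim$kinetics))
          list(tau0 = 50, q_tau = 0.37, delta0 = 10, q_delta = 0.47)
          else sim$kinetics,
        g_max_nS = if (is.null(sim$g_max_nS)) 5 else sim$g_max_nS,
        g_leak_nS = if (is.null(sim$g_leak_nS)) 0 else sim$g_leak_nS,
        noise_sd_pA = if (is.null(sim$noise_sd_pA)) 0 else sim$noise_sd_pA,
        seed = seed + i)
    })
  }

  fits <- lapply(seq_along(families), function(i) {
    fam <- families[[i]]
    label <- sprintf("condition %d (pH_o %g / pH_i %g)", i, fam$pH_o, fam$pH_i)
    tryCatch({
      if (!is.null(fam$subsweeps)) {
        say("stage leak-subtract: %s", label)
        fam <- p4_leak_subtract(fam)
      }
      vrev <- nernst_potential(fam$pH_o, fam$pH_i, fam$temperature_K)
      ss <- steady_state_currents(fam)
      ss <- ss[abs(ss$V_mV - vrev) >= 1, ]   # guard band around V_rev
      say("stage gv: %s (%d points)", label, nrow(ss))
      gv <- conductance_from_iv(ss, vrev)
      bf <- fit_boltzmann(gv, fam$temperature_K)
      tf <- tryCatch(fit_threshold(gv, fraction = v_thr_fraction,
                                   g_max = bf$g_max,
                                   temperature_K = fam$temperature_K),
                     error = function(e) NULL)
      list(pH_o = fam$pH_o, pH_i = fam$pH_i,
           delta_pH = fam$pH_o - fam$pH_i, v_rev_mV = vrev,
           boltzmann = bf, threshold = tf)
    }, error = function(e)
      stop("run_pipeline: stage failed for ", label, ": ",
           conditionMessage(e)))
  })

  tab <- do.call(rbind, lapply(fits, function(f) {
    se <- if (!is.null(f$boltzmann$vcov))
      sqrt(diag(f$boltzmann$vcov))[["v_half"]] else NA_real_
    data.frame(pH_o = f$pH_o, pH_i = f$pH_i, delta_pH = f$delta_pH,
               V_half_mV = f$boltzmann$v_half, V_half_se_mV = se,
               q_e0 = f$boltzmann$q,
               V_thr_mV = if (is.null(f$threshold)) NA_real_
                          else f$threshold$v_thr)
  }))
  # replicate conditions at one delta_pH combine as mean +/- sem downstream;
  # the per-recording table keeps every fit traceable to its input
  tab <- tab[order(tab$delta_pH), ]

  model <- config$model
  if (is.null(model) && !is.null(config$simulate) &&
      inherits(config$simulate$gating, "allosteric_params"))
    model <- config$simulate$gating
  model_table <- NULL; comparison <- NULL
  if (inherits(model, "allosteric_params")) {
    say("stage model: predicting V0.5 per condition")
    model_table <- v_half_vs_delta_ph(model, tab$pH_o, tab$pH_i)
    comparison <- compare_model_to_vhalf(tab, model,
                                         data.frame(pH_o = tab$pH_o,
                                                    pH_i = tab$pH_i))
  }

  structure(list(fits = fits, table = tab, model_table = model_table,
                 comparison = comparison,
                 provenance = list(seed = seed,
                                   config_hash = .config_hash(config),
                                   package_version =
                                     as.character(utils::packageVersion("hvgate")))),
            class = "study_result")
}

.config_hash <- function(config) {
  # strip environments (closures) that would defeat stable serialization
  js <- jsonlite::serializeJSON(rapply(config, function(x) x,
                                       classes = "ANY", how = "replace"))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Study result: %d conditions (seed %s, config %s)\n",
              nrow(x$table), x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  print(x$table, row.names = FALSE)
  if (!is.null(x$comparison))
    cat(sprintf("Model comparison RMS: %.3g mV\n", x$comparison$rms))
  invisible(x)
}

#' Compare measured V0.5 values with the allosteric-model prediction
#'
#' Evaluates the model V0.5 at each (pH_o, pH_i) pair and reports per-point
#' residuals (measured - predicted) and their root-mean-square.
#'
#' @param table Data frame with columns \code{delta_pH} and \code{V_half_mV}
#'   (optionally \code{V_half_se_mV}).
#' @param params An [allosteric_params()] object.
#' @param ph_pairs Data frame with columns \code{pH_o}, \code{pH_i}, one row
#'   per row of \code{table}.
#' @return List with \code{residuals} (data frame) and \code{rms} (mV).
#' @export
compare_model_to_vhalf <- function(table, params, ph_pairs) {
  stopifnot(inherits(params, "allosteric_params"))
  table <- as.data.frame(table); ph_pairs <- as.data.frame(ph_pairs)
  if (nrow(table) != nrow(ph_pairs))
    stop("compare_model_to_vhalf: table and ph_pairs lengths differ")
  pred <- solve_v_half(params, ph_pairs$pH_o, ph_pairs$pH_i)
  res <- data.frame(delta_pH = ph_pairs$pH_o - ph_pairs$pH_i,
                    measured_mV = table$V_half_mV,
                    predicted_mV = pred,
                    residual_mV = table$V_half_mV - pred)
  list(residuals = res, rms = sqrt(mean(res$residual_mV^2)))
}
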