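#' Fit a first-order deacylation decay curve
#'
#' Nonlinear least squares on S(t) = S0 * exp(-k t) (no plateau term),
#' matching the first-order model used for deacylation assays. Starting
#' values come from log-linear regression on the positive fractions;
#' `k_obs >= 0` is enforced as a box constraint. If the optimiser hits its
#' iteration cap the best estimate is returned with `converged = FALSE`.
#'
#' @param t numeric vector of times (minutes), non-negative, strictly
#'   increasing, length >= 3.
#' @param fraction substrate fraction remaining at each time, in `[0, 1.2]`.
#' @param max_iter optimiser iteration cap (default 100).
#' @return a [DecayFit-class].
#' @examples
#' tc <- genDecaySeries(k = 0.1, timepoints = 0:7 * 2, noise_sd = 0, seed = 1)
#' fitDecay(tc$t_min, tc$fraction_remaining)
#' @export
fitDecay <- function(t, fraction, max_iter = 100L) {
  stopifnot(length(t) == length(fraction), length(t) >= 3,
            all(t >= 0), all(diff(t) > 0))
  # log-linear start: log S = log S0 - k t on positive fractions
  pos <- fraction > 0
  if (sum(pos) >= 2) {
    co <- stats::coef(stats::lm(log(fraction[pos]) ~ t[pos]))
    s0_start <- min(1.2, max(1e-3, exp(co[1])))
    k_start <- max(0, -co[2])
  } else {
    s0_start <- max(fraction, 1e-3); k_start <- 1
  }
  df <- data.frame(t = t, y = fraction)
  fit <- tryCatch(
    withCallingHandlers(
      minpack.lm::nlsLM(y ~ s0 * exp(-k * t), data = df,
                        start = list(s0 = s0_start, k = k_start),
                        lower = c(s0 = 1e-6, k = 0),
                        upper = c(s0 = 1.2, k = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = max_iter)),
      # the iteration-cap warning is folded into `converged`
      warning = function(w) {
        if (grepl("maxiter|iterations", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- s0_start * exp(-k_start * t)
    return(new("DecayFit", k_obs = k_start, s0 = s0_start,
               rmse = sqrt(mean((fraction - pred)^2)), converged = FALSE))
  }
  cf <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  new("DecayFit", k_obs = unname(cf["k"]), s0 = unname(cf["s0"]),
      rmse = sqrt(mean(stats::resid(fit)^2)), converged = isTRUE(conv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit every time course in a long-format kinetics table
#'
#' @param data long-format data.frame with columns `substrate`,
#'   `enzyme_conc_nM`, `eftu`, `t_min`, `fraction_remaining`.
#' @return data.frame with one row per (substrate, enzyme_conc_nM, eftu):
#'   `k_obs`, `s0`, `rmse`, `converged`, `final_fraction`.
#' @export
fitDecayTable <- function(data) {
  need <- c("substrate", "enzyme_conc_nM", "eftu", "t_min",
            "fraction_remaining")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("kinetics table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  sp <- split(data, list(data$substrate, data$enzyme_conc_nM, data$eftu),
              drop = TRUE)
  out <- lapply(sp, function(d) {
    d <- d[order(d$t_min), ]
    f <- fitDecay(d$t_min, d$fraction_remaining)
    data.frame(substrate = d$substrate[1], enzyme_conc_nM = d$enzyme_conc_nM[1],
               eftu = d$eftu[1], k_obs = f@k_obs, s0 = f@s0, rmse = f@rmse,
               converged = f@converged,
               final_fraction = d$fraction_remaining[nrow(d)],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$substrate, res$eftu, res$enzyme_conc_nM), ]
}

#' Minimal effective enzyme concentration for one substrate
#'
#' The smallest tested enzyme concentration at which the substrate is
#' depleted by at least `depletion_threshold` (fraction of the initial
#' substrate) at the final timepoint. This operationalises "the enzyme acts
#' on the substrate at X nM". Returns `NA` if no tested concentration
#' qualifies.
#'
#' @param series long-format data.frame for one substrate (columns
#'   `enzyme_conc_nM`, `t_min`, `fraction_remaining`), spanning >= 2
#'   enzyme concentrations.
#' @param depletion_threshold default 0.5.
#' @return numeric(1) concentration in nM, or `NA_real_`.
#' @export
minEffectiveConc <- function(series, depletion_threshold = 0.5) {
  concs <- sort(unique(series$enzyme_conc_nM))
  if (length(concs) < 2)
    stop("series must span >= 2 enzyme concentrations")
  for (cc in concs) {
    d <- series[series$enzyme_conc_nM == cc, , drop = FALSE]
    d <- d[order(d$t_min), , drop = FALSE]
    depletion <- 1 - d$fraction_remaining[nrow(d)]
    if (depletion >= depletion_threshold) return(cc)
  }
  NA_real_
}

#' Substrate discrimination factor
#'
#' Ratio of the minimal effective enzyme concentration on the cognate
#' substrate to that on the non-cognate substrate: how many fold more
#' enzyme the cognate substrate tolerates. For ATD acting on
#' L-Ala-tRNA-Thr(G4:U69) (non-cognate, preferred) versus
#' L-Thr-tRNA-Thr(G4:U69) (cognate) this is at least 50 without EF-Tu and
#' beyond 100 with activated EF-Tu.
#'
#' @param noncognate,cognate long-format series (see [minEffectiveConc()]).
#' @param depletion_threshold passed through.
#' @return list with `conc_noncognate`, `conc_cognate`, `factor`
#'   (`NA` with a message attribute when either side is undefined).
#' @export
discriminationFactor <- function(noncognate, cognate,
                                 depletion_threshold = 0.5) {
  cn <- minEffectiveConc(noncognate, depletion_threshold)
  cc <- minEffectiveConc(cognate, depletion_threshold)
  if (is.na(cn) || is.na(cc)) {
    out <- list(conc_noncognate = cn, conc_cognate = cc, factor = NA_real_)
    attr(out, "message") <- "minimal effective concentration undefined on one side"
    return(out)
  }
  list(conc_noncognate = cn, conc_cognate = cc, factor = cc / cn)
}

#' EF-Tu protection factor
#'
#' Ratio of the minimal effective enzyme concentration in the presence of
#' EF-Tu to that without it, on matched concentration ladders for one
#' substrate: how many fold more enzyme is needed to attack the substrate
#' once EF-Tu sequesters it.
#'
#' @param with_eftu,without_eftu long-format series for the same substrate.
#' @param depletion_threshold passed through.
#' @return list with `conc_with`, `conc_without`, `factor`.
#' @export
protectionFactor <- function(with_eftu, without_eftu,
                             depletion_threshold = 0.5) {
  cw <- minEffectiveConc(with_eftu, depletion_threshold)
  co <- minEffectiveConc(without_eftu, depletion_threshold)
  if (is.na(cw) || is.na(co)) {
    out <- list(conc_with = cw, conc_without = co, factor = NA_real_)
    attr(out, "message") <- "minimal effective concentration undefined on one side"
    return(out)
  }
  list(conc_with = cw, conc_without = co, factor = cw / co)
}

#' Read a long-format deacylation kinetics table
#'
#' @param path TSV with columns `substrate`, `enzyme_conc_nM`, `eftu`,
#'   `t_min`, `fraction_remaining`.
#' @return data.frame.
#' @export
readKineticsTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("substrate", "enzyme_conc_nM", "eftu", "t_min",
            "fraction_remaining")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("kinetics table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  tab
}
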