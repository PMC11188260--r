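## ODE model of mRNA abundance under coordinated transcriptional and AS-NMD
## repression:
##
##   dR/dt = r_t(t) * r_n(t) * v_sr  -  k_dr * R(t),   k_dr = ln2 / t_half
##
## r_t is a transcriptional repression factor and r_n an AS-NMD repression
## factor (the fraction of transcription yielding productive, NMD-escaping
## mRNA); both are piecewise-constant schedules in [0, 1]. NMD-sensitive
## isoforms are assumed much less stable than productive mRNA and do not
## contribute to R. Time is in hours internally.

#' mRNA decay constant from half-life
#' @param t_half half-life in hours (> 0).
#' @return k_dr in 1/h: `log(2) / t_half`.
#' @export
decay_constant <- function(t_half) {
  if (any(t_half <= 0)) stop("half-life must be positive")
  log(2) / t_half
}

#' Steady-state mRNA abundance
#' @param v_sr synthesis rate (molecules/cell/h).
#' @param r_t,r_n repression factors in \[0, 1\].
#' @param k_dr decay constant (1/h, > 0).
#' @return `R* = r_t * r_n * v_sr / k_dr` (molecules/cell).
#' @export
steady_state <- function(v_sr, r_t, r_n, k_dr) {
  if (any(k_dr <= 0)) stop("no steady state without decay (k_dr must be > 0)")
  r_t * r_n * v_sr / k_dr
}

#' Piecewise-constant schedule
#'
#' A factor taking `values[i]` on `[breaks[i], breaks[i+1])` and
#' `values[n]` from `breaks[n]` on. `breaks[1]` is the schedule origin.
#'
#' @param breaks increasing time breakpoints (h), first = origin.
#' @param values factor values in \[0, 1\], same length as `breaks`.
#' @export
piecewise_schedule <- function(breaks, values) {
  stopifnot(length(breaks) == length(values), !is.unsorted(breaks),
            all(values >= 0 & values <= 1))
  structure(list(breaks = as.numeric(breaks), values = as.numeric(values)),
            class = "piecewise_schedule")
}

#' Evaluate a schedule at times
#' @param sched [piecewise_schedule()]
#' @param t times (h), not before the schedule origin.
#' @export
schedule_value <- function(sched, t) {
  idx <- findInterval(t, sched$breaks)
  if (any(idx == 0)) stop("time before schedule origin")
  sched$values[idx]
}

#' Model parameter set
#'
#' @param v_sr synthesis rate (molecules/cell/h, > 0).
#' @param t_half mRNA half-life (h, > 0); `k_dr` is derived as
#'   `log(2)/t_half`.
#' @param r_t_schedule,r_n_schedule [piecewise_schedule()]s of the
#'   transcriptional and AS-NMD repression factors.
#' @param scenario free-text label.
#' @export
model_params <- function(v_sr, t_half, r_t_schedule, r_n_schedule,
                         scenario = "custom") {
  stopifnot(v_sr > 0, t_half > 0,
            inherits(r_t_schedule, "piecewise_schedule"),
            inherits(r_n_schedule, "piecewise_schedule"))
  structure(list(v_sr = v_sr, t_half = t_half, k_dr = decay_constant(t_half),
                 r_t_schedule = r_t_schedule, r_n_schedule = r_n_schedule,
                 scenario = scenario),
            class = "model_params")
}

#' Named parameter presets for the downregulation model
#'
#' Published transcriptome-wide medians parameterise the `"genomewide"`
#' preset (v_sr = 1.76 molecules/cell/h, the median transcription rate
#' measured in mouse NIH 3T3 cells; t_half = 7.08 h, the median half-life in
#' proliferating and differentiating mouse ESCs). The `"gene-averaged"`
#' preset instead averages the three experimentally dissected target genes
#' (v_sr = 2.63, t_half = 5.11 h). In both, r_t falls 1 -> 0.39 (mean
#' late/early expression ratio of the NS-CE mutants) and r_n falls
#' 0.78 -> 0.12 (from `1 - PSI_CHX/100` averaged over early and late
#' timepoints), with onsets inside the day 2-4 window set by the scenario:
#' \describe{
#'   \item{asnmd-only}{r_n drops at 60 h; r_t stays 1.}
#'   \item{asnmd-precedes}{r_n at 48 h, r_t at 72 h.}
#'   \item{coincident}{both at 60 h.}
#'   \item{asnmd-follows}{r_t at 48 h, r_n at 72 h.}
#' }
#'
#' @param scenario one of the four coordination scenarios.
#' @param preset `"genomewide"` (default) or `"gene-averaged"`.
#' @param r_t_final,r_n_initial,r_n_final overridable factor values.
#' @param t_asnmd,t_transcription overridable onset times (h).
#' @return [model_params()]
#' @export
model_preset <- function(scenario = c("asnmd-only", "asnmd-precedes",
                                      "coincident", "asnmd-follows"),
                         preset = c("genomewide", "gene-averaged"),
                         r_t_final = 0.39, r_n_initial = 0.78,
                         r_n_final = 0.12, t_asnmd = NULL,
                         t_transcription = NULL) {
  scenario <- match.arg(scenario)
  preset <- match.arg(preset)
  pars <- switch(preset,
                 "genomewide" = c(v_sr = 1.76, t_half = 7.08),
                 "gene-averaged" = c(v_sr = 2.63, t_half = 5.11))
  onsets <- switch(scenario,
                   "asnmd-only"     = list(asnmd = 60, transcription = NA),
                   "asnmd-precedes" = list(asnmd = 48, transcription = 72),
                   "coincident"     = list(asnmd = 60, transcription = 60),
                   "asnmd-follows"  = list(asnmd = 72, transcription = 48))
  if (!is.null(t_asnmd)) onsets$asnmd <- t_asnmd
  if (!is.null(t_transcription)) onsets$transcription <- t_transcription
  r_n <- piecewise_schedule(c(0, onsets$asnmd), c(r_n_initial, r_n_final))
  r_t <- if (is.na(onsets$transcription))
    piecewise_schedule(0, 1)
  else piecewise_schedule(c(0, onsets$transcription), c(1, r_t_final))
  model_params(v_sr = pars[["v_sr"]], t_half = pars[["t_half"]],
               r_t_schedule = r_t, r_n_schedule = r_n, scenario = scenario)
}

#' Simulate the downregulation ODE
#'
#' Integrates `dR/dt = r_t(t) r_n(t) v_sr - k_dr R` over `t_grid` with an
#' adaptive Runge-Kutta scheme (`deSolve::ode`, `ode45`), segment-wise
#' between schedule breakpoints so discontinuities never cross an integrator
#' step. `R(0)` defaults to the initial steady state.
#'
#' @param params [model_params()]
#' @param t_grid increasing times (h), starting at the schedule origin.
#' @param R0 initial abundance; NULL for the initial steady state.
#' @return data.frame: time, R, r_t, r_n.
#' @export
simulate_downregulation <- function(params, t_grid, R0 = NULL) {
  stopifnot(inherits(params, "model_params"), !is.unsorted(t_grid))
  t_grid <- as.numeric(t_grid)
  r_t0 <- schedule_value(params$r_t_schedule, t_grid[1])
  r_n0 <- schedule_value(params$r_n_schedule, t_grid[1])
  if (is.null(R0))
    R0 <- steady_state(params$v_sr, r_t0, r_n0, params$k_dr)
  brk <- sort(unique(c(params$r_t_schedule$breaks,
                       params$r_n_schedule$breaks)))
  brk <- brk[brk > t_grid[1] & brk < t_grid[length(t_grid)]]
  seg_bounds <- c(t_grid[1], brk, t_grid[length(t_grid)])
  R <- numeric(length(t_grid))
  state <- R0
  for (k in seq_len(length(seg_bounds) - 1)) {
    a <- seg_bounds[k]; b <- seg_bounds[k + 1]
    rt <- schedule_value(params$r_t_schedule, a)
    rn <- schedule_value(params$r_n_schedule, a)
    sel <- which(t_grid >= a & t_grid <= b)
    times <- sort(unique(c(a, t_grid[sel], b)))
    sol <- deSolve::ode(
      y = c(R = state), times = times,
      func = function(t, y, p) list(p$rt * p$rn * p$v - p$k * y),
      parms = list(rt = rt, rn = rn, v = params$v_sr, k = params$k_dr),
      method = "ode45", atol = 1e-10, rtol = 1e-10)
    R[sel] <- sol[match(t_grid[sel], sol[, "time"]), "R"]
    state <- unname(sol[nrow(sol), "R"])
  }
  R[match(t_grid[1], t_grid)] <- R0
  data.frame(time = t_grid, R = R,
             r_t = schedule_value(params$r_t_schedule, t_grid),
             r_n = schedule_value(params$r_n_schedule, t_grid))
}

#' Estimate the AS-NMD repression factor from NMD-blocked inclusion levels
#'
#' `r_n = 1 - mean(PSI_CHX)/100`: the productive fraction of transcription
#' inferred from percent-spliced-in of the poison exon measured under NMD
#' inhibition (cycloheximide), averaged over the supplied measurements.
#'
#' @param psi_chx_percent PSI values in percent (0-100).
#' @export
estimate_rn <- function(psi_chx_percent) {
  if (any(psi_chx_percent < 0 | psi_chx_percent > 100))
    stop("PSI percent outside [0, 100]")
  1 - mean(psi_chx_percent) / 100
}

#' Estimate the transcriptional repression factor from expression ratios
#'
#' Mean over clones/genes of (mean late expression)/(mean early expression),
#' e.g. days 5-6 over days 0-1 in NS-CE-mutant lines, where AS-NMD cannot
#' act and residual downregulation is attributed to transcription.
#'
#' @param expr_late,expr_early lists (or vectors) of per-clone expression
#'   level vectors; element i of each describes the same clone.
#' @return mean ratio; clones with zero early expression are excluded with a
#'   warning.
#' @export
estimate_rt <- function(expr_late, expr_early) {
  if (!is.list(expr_late)) expr_late <- list(expr_late)
  if (!is.list(expr_early)) expr_early <- list(expr_early)
  stopifnot(length(expr_late) == length(expr_early))
  ratios <- vapply(seq_along(expr_late), function(i) {
    e <- mean(expr_early[[i]])
    if (e == 0) return(NA_real_)
    mean(expr_late[[i]]) / e
  }, numeric(1))
  if (anyNA(ratios)) {
    warning(sum(is.na(ratios)), " clone(s) with zero early expression excluded")
    ratios <- ratios[!is.na(ratios)]
  }
  if (!length(ratios)) stop("no usable clones")
  mean(ratios)
}

#' Wild-type/mutant dichotomy point of an expression time course
#'
#' Given mutant expression series normalised to the wild type (one series
#' per clone on a shared time grid), returns the timepoint immediately
#' preceding the first grid point at which the clone-averaged series exceeds
#' `threshold`. The threshold defaults to the median of all pooled
#' normalised values. Returns NA when the series never exceeds it.
#'
#' @param normalized mutant/WT expression: matrix clones x timepoints (or a
#'   vector for one clone).
#' @param times timepoints matching the columns.
#' @param threshold exceedance threshold; NULL for the pooled median.
#' @return list: dichotomy (timepoint or NA), threshold used, first
#'   exceedance timepoint (or NA).
#' @export
dichotomy_point <- function(normalized, times, threshold = NULL) {
  if (is.vector(normalized)) normalized <- matrix(normalized, nrow = 1)
  if (!length(normalized)) stop("empty series")
  stopifnot(ncol(normalized) == length(times))
  if (is.null(threshold)) threshold <- stats::median(as.numeric(normalized))
  avg <- colMeans(normalized)
  ex <- which(avg > threshold)
  if (!length(ex))
    return(list(dichotomy = NA_real_, threshold = threshold,
                first_exceedance = NA_real_))
  first <- min(ex)
  list(dichotomy = if (first == 1) NA_real_ else times[first - 1],
       threshold = threshold, first_exceedance = times[first])
}
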