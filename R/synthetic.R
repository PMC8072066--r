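# Synthetic cohort generator: cross-sectional mouse cohorts with the
# statistical structure the analysis assumes (one mouse per time point,
# binomial sampling noise on labeled frequencies, lognormal multiplicative
# noise on compartment counts), so that the whole pipeline and inference
# can be exercised without any external data.

#' Cohort design for the synthetic generator
#'
#' Describes one labeling experiment: which days mice are sacrificed on and
#' how many per day, the initial labeled frequency of each model
#' compartment (the labeling fingerprint of the Cre driver), the
#' tamoxifen-effect offset added to recorded times, and the measurement
#' noise model (cells sampled per gate for binomial frequency noise;
#' log-SD of lognormal count noise).
#'
#' @param dataset Dataset/driver identifier.
#' @param times Measurement days since effective induction (model time).
#' @param mice_per_time Integer vector (recycled) of mice per time point,
#'   each `>= 1`.
#' @param f0 Initial labeled frequencies `(HSC-U, HSC-D, ST-HSC, MPP)`.
#' @param time_zero_offset Days added to recorded times (undone by
#'   [adjust_time_zero()]).
#' @param cells_sampled Named vector of cells sampled per observed gate;
#'   `Inf` disables frequency noise.
#' @param count_log_sd Log-SD of lognormal count noise; `0` disables it.
#' @return An object of class `hsc_cohort_design`.
#' @export
cohort_design <- function(dataset, times, mice_per_time, f0,
                          time_zero_offset = 2,
                          cells_sampled = c("HSC" = 200, "ST-HSC" = 200,
                                            "MPP" = 1000),
                          count_log_sd = 0.2) {
  times <- as.numeric(times)
  mice <- as.integer(rep_len(mice_per_time, length(times)))
  if (any(!is.finite(times)) || any(times < 0))
    stop("`times` must be non-negative")
  if (any(mice < 1)) stop("`mice_per_time` must be >= 1")
  if (length(f0) != 4 || any(f0 < 0) || any(f0 > 1))
    stop("`f0` must be 4 frequencies in [0, 1]")
  if (!all(OBS_COMPARTMENTS %in% names(cells_sampled)))
    stop("`cells_sampled` must name HSC, ST-HSC and MPP")
  structure(list(dataset = dataset, times = times, mice_per_time = mice,
                 f0 = as.numeric(f0), time_zero_offset = time_zero_offset,
                 cells_sampled = cells_sampled,
                 count_log_sd = count_log_sd),
            class = "hsc_cohort_design")
}

#' @export
print.hsc_cohort_design <- function(x, ...) {
  cat("Cohort design '", x$dataset, "': ", sum(x$mice_per_time),
      " mice over ", length(x$times), " time points (",
      min(x$times), "-", max(x$times), " d)\n", sep = "")
  cat("  f0 (U, D, ST, MPP):", paste(x$f0, collapse = ", "),
      "| U:D ratio:",
      if (x$f0[2] > 0) signif(x$f0[1] / x$f0[2], 3) else "unbounded", "\n")
  invisible(x)
}

#' Preset cohort designs
#'
#' Named designs emulating the three published Cre-driver experiments and
#' the two-label toy comparison:
#' * `"tie2-like"`: 8 pooled time points with per-bin mouse numbers
#'   (41, 61, 21, 8, 39, 34, 21, 17), low overall HSC labeling with a
#'   21:1 HSC-U:HSC-D labeling ratio, 2-day offset.
#' * `"fgd5-like"`: 8 time points of 7 mice, high labeling with a 4:1
#'   ratio, 2-day offset.
#' * `"krt18-like"`: 6 time points of 3 mice (18 total), 30:1 ratio,
#'   1-day offset.
#' * `"toy-I"` / `"toy-J"`: identical sampling, labeling `(50%, 0%)`
#'   versus `(50%, 50%)` of HSC-U/HSC-D, noise switched off.
#'
#' @param name A preset name, or `NULL` for the full named list.
#' @return A `hsc_cohort_design` (or named list of all presets).
#' @export
preset_designs <- function(name = NULL) {
  toy_noise <- c("HSC" = Inf, "ST-HSC" = Inf, "MPP" = Inf)
  presets <- list(
    "tie2-like" = cohort_design(
      "tie2-like",
      times = c(10, 38, 62, 86, 116, 141, 169, 198),
      mice_per_time = c(41, 61, 21, 8, 39, 34, 21, 17),
      f0 = c(0.21, 0.01, 0.01, 0.005),
      time_zero_offset = 2),
    "fgd5-like" = cohort_design(
      "fgd5-like",
      times = c(7, 14, 28, 56, 84, 140, 196, 252),
      mice_per_time = 7,
      f0 = c(0.60, 0.15, 0.05, 0.02),
      time_zero_offset = 2),
    "krt18-like" = cohort_design(
      "krt18-like",
      times = c(7, 14, 28, 56, 112, 196),
      mice_per_time = 3,
      f0 = c(0.45, 0.015, 0.005, 0.002),
      time_zero_offset = 1),
    "toy-I" = cohort_design(
      "toy-I", times = seq(0, 280, by = 20), mice_per_time = 5,
      f0 = c(0.5, 0, 0, 0), time_zero_offset = 0,
      cells_sampled = toy_noise, count_log_sd = 0),
    "toy-J" = cohort_design(
      "toy-J", times = seq(0, 280, by = 20), mice_per_time = 5,
      f0 = c(0.5, 0.5, 0, 0), time_zero_offset = 0,
      cells_sampled = toy_noise, count_log_sd = 0))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Generate one synthetic cross-sectional cohort
#'
#' Each mouse is measured once, at its design time point, in the three
#' observable gates (HSC = aggregate of the hidden HSC-U/HSC-D
#' subcompartments, ST-HSC, MPP). Expected frequencies and counts come
#' from the model; the observed frequency is a binomial draw of labeled
#' cells among `cells_sampled` cells divided by that number, and the
#' observed count is the expected count times lognormal noise. Recorded
#' times include the design's time-zero offset, so tables round-trip
#' through the preprocessing pipeline.
#'
#' @param rates True [kinetic_rates].
#' @param n0 True initial expected counts (length 4).
#' @param design An [cohort_design] (or preset name).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return An `hsc_observations` data frame with attributes `seed` and
#'   `truth` (the generating parameters).
#' @export
generate_cohort <- function(rates, n0 = default_initial_counts(), design,
                            seed = 1) {
  if (is.character(design)) design <- preset_designs(design)
  stopifnot(inherits(design, "hsc_cohort_design"))
  init <- initial_state(n0, design$f0, rates$topology)
  check_dims(rates, init)
  set.seed(as.integer(seed))

  cur <- model_curves(rates$kappa, rates$alpha, init$n0, init$f0,
                      design$times)
  gate <- hsc_gate_indices(rates$topology)
  st <- match("ST-HSC", rates$topology$compartments)
  mpp <- match("MPP", rates$topology$compartments)
  n_exp <- cbind(rowSums(cur$n[, gate, drop = FALSE]), cur$n[, st],
                 cur$n[, mpp])
  f_exp <- cbind(rowSums(cur$l[, gate, drop = FALSE]) /
                   rowSums(cur$n[, gate, drop = FALSE]),
                 cur$f[, st], cur$f[, mpp])

  n_mice <- sum(design$mice_per_time)
  ti <- rep(seq_along(design$times), design$mice_per_time)
  mouse <- sprintf("%s-m%04d", design$dataset, seq_len(n_mice))
  per_comp <- lapply(1:3, function(ci) {
    C <- design$cells_sampled[[OBS_COMPARTMENTS[ci]]]
    fo <- if (is.infinite(C)) f_exp[ti, ci]
          else rbinom(n_mice, C, f_exp[ti, ci]) / C
    no <- n_exp[ti, ci] *
      (if (design$count_log_sd > 0) rlnorm(n_mice, 0, design$count_log_sd)
       else 1)
    data.frame(mouse_id = mouse, dataset = design$dataset,
               time_days = design$times[ti] + design$time_zero_offset,
               compartment = OBS_COMPARTMENTS[ci],
               frequency = pmin(1, pmax(0, fo)), count = no,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_comp)
  out <- out[order(match(out$mouse_id, mouse)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hsc_observations", "data.frame")
  attr(out, "seed") <- as.integer(seed)
  attr(out, "truth") <- list(rates = rates, n0 = n0, f0 = design$f0,
                             design = design$dataset)
  out
}

#' Generate several cohorts sharing one set of kinetics
#'
#' All tables are simulated from the same kinetics and initial compartment
#' sizes; designs differ only in initial labeling and cohort structure.
#' This mirrors the working assumption that distinct Cre-driver
#' experiments probe a single set of stem-cell kinetics.
#'
#' @inheritParams generate_cohort
#' @param designs List of [cohort_design]s (or preset names); at least 2.
#' @param seed Base seed; design `i` uses `seed + i - 1`.
#' @return A named list of `hsc_observations` tables.
#' @export
generate_multi_dataset <- function(rates, n0 = default_initial_counts(),
                                   designs, seed = 1) {
  if (length(designs) < 2) stop("supply at least two designs")
  designs <- lapply(designs, function(d)
    if (is.character(d)) preset_designs(d) else d)
  out <- lapply(seq_along(designs), function(i)
    generate_cohort(rates, n0, designs[[i]], seed = seed + i - 1L))
  names(out) <- vapply(designs, `[[`, "", "dataset")
  out
}

#' Write the generating truth as a JSON manifest
#'
#' Records the kinetics, initial sizes and per-design initial labeling
#' used to simulate a set of cohorts, for later parameter-recovery checks.
#'
#' @param rates True [kinetic_rates].
#' @param n0 True initial counts.
#' @param designs List of [cohort_design]s.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(rates, n0, designs, path) {
  manifest <- list(
    compartments = rates$topology$compartments,
    alpha = rates$alpha, beta = rates$beta, kappa = rates$kappa,
    lambda = rates$lambda, delta = rates$delta, n0 = n0,
    designs = lapply(designs, function(d) {
      if (is.character(d)) d <- preset_designs(d)
      list(dataset = d$dataset, times = d$times,
           mice_per_time = d$mice_per_time, f0 = d$f0,
           time_zero_offset = d$time_zero_offset)
    }))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
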