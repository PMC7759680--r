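# Seeded simulation designs with retained ground-truth counterfactuals.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

noise_sd <- function(value, as_variance) if (as_variance) sqrt(value) else value

#' Specification of the binary-treatment simulation
#'
#' Ten-thousand subjects with 30 standard-normal covariates; latent outcome
#' surfaces quadratic in the first covariate with an interaction under
#' treatment,
#' \deqn{\hat y^0 = 0.05 + 0.4 x_1^2 + 0.25 x_2 + n_0,\quad
#'       \hat y^1 = 0.15 + 0.5 x_1^2 + 0.25 x_1 x_2 + 0.25 x_2 + n_1,}
#' thresholded at 0.5 into binary potential outcomes.  Treatment is assigned
#' `Bern(sigmoid(w'x + e))` with `w ~ U(-0.1, 0.1)^q` drawn once per dataset.
#'
#' @param n subjects.
#' @param q covariates.
#' @param noise_value second parameter of the outcome noise distribution
#'   `N(0, 0.05)`.
#' @param noise_as_variance interpret `noise_value` (and the assignment noise
#'   value) as a variance rather than a standard deviation.
#' @param assign_weight_range range of the uniform assignment weights.
#' @param assign_noise_value second parameter of the assignment noise
#'   `N(0, 0.1)`.
#' @param threshold binarization threshold for the latent surfaces.
#' @param eval_subset size of the held-out evaluation subset used by effect
#'   reports.
#' @param seed integer seed.
#' @return An object of class `binary_sim_spec`.
#' @export
binary_sim_spec <- function(n = 10000L, q = 30L, noise_value = 0.05,
                            noise_as_variance = FALSE,
                            assign_weight_range = c(-0.1, 0.1),
                            assign_noise_value = 0.1, threshold = 0.5,
                            eval_subset = 500L, seed = 1L) {
  stopifnot(n > 0, threshold > 0, threshold < 1)
  structure(list(n = as.integer(n), q = as.integer(q),
                 noise_value = noise_value,
                 noise_as_variance = isTRUE(noise_as_variance),
                 assign_weight_range = assign_weight_range,
                 assign_noise_value = assign_noise_value,
                 threshold = threshold, eval_subset = as.integer(eval_subset),
                 seed = as.integer(seed)),
            class = "binary_sim_spec")
}

#' Specification of the continuous-dose simulation
#'
#' One standard-normal covariate; dose from the shifted exponential with
#' density `exp(-(t - 1))`, `t >= 1`; covariate surface
#' `f(x) = 1 / (2 + exp(-20 (x - 1/3)))`; dose effect `g(t) = 0.1 t^2`;
#' potential outcomes `y0 = 0.3 + f(x) + n0`, `y1 = 0.3 + f(x) + g(t) + n1`;
#' fair-coin assignment.  The outcome noise `N(0, 0.01)` is read as a
#' variance (sd 0.1) by default; see the methods vignette.
#'
#' @param n subjects.
#' @param noise_value second parameter of the outcome noise `N(0, 0.01)`.
#' @param noise_as_variance interpret `noise_value` as a variance.
#' @param assign_prob probability of assignment to the treated (dosed) arm.
#' @param seed integer seed.
#' @return An object of class `continuous_sim_spec`.
#' @export
continuous_sim_spec <- function(n = 10000L, noise_value = 0.01,
                                noise_as_variance = TRUE, assign_prob = 0.5,
                                seed = 1L) {
  stopifnot(n > 0, assign_prob > 0, assign_prob < 1)
  structure(list(n = as.integer(n), noise_value = noise_value,
                 noise_as_variance = isTRUE(noise_as_variance),
                 assign_prob = assign_prob, seed = as.integer(seed)),
            class = "continuous_sim_spec")
}

#' Simulate the binary-treatment design
#'
#' Generates the observable [treatment_frame()] (arm 1 = treated, arm 2 =
#' control) and, separately, the ground truth: both binary potential
#' outcomes, the latent surfaces and the individualized treatment effect
#' `ITE = y1 - y0` in `{-1, 0, 1}`, plus the index of a fixed evaluation
#' subset.  The observable frame never contains counterfactuals.
#'
#' @param spec a [binary_sim_spec()].
#' @return `list(frame, truth)` where `truth` has `Y0`, `Y1`, `ITE`,
#'   `surface0`, `surface1`, `eval_idx`.
#' @export
simulate_binary <- function(spec) {
  stopifnot(inherits(spec, "binary_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n; q <- spec$q
    sdn <- noise_sd(spec$noise_value, spec$noise_as_variance)
    sda <- noise_sd(spec$assign_noise_value, spec$noise_as_variance)
    X <- matrix(rnorm(n * q), n, q)
    s0 <- 0.05 + 0.4 * X[, 1]^2 + 0.25 * X[, 2] + rnorm(n, 0, sdn)
    s1 <- 0.15 + 0.5 * X[, 1]^2 + 0.25 * X[, 1] * X[, 2] + 0.25 * X[, 2] +
      rnorm(n, 0, sdn)
    y0 <- as.numeric(s0 >= spec$threshold)
    y1 <- as.numeric(s1 >= spec$threshold)
    w <- runif(q, spec$assign_weight_range[1], spec$assign_weight_range[2])
    p_treat <- plogis(drop(X %*% w) + rnorm(n, 0, sda))
    treated <- rbinom(n, 1, p_treat)
    eta <- ifelse(treated == 1, 1L, 2L)
    Y_f <- ifelse(treated == 1, y1, y0)
    frame <- treatment_frame(X, eta, Y_f, K = 2L,
                             arm_labels = c("treated", "control"),
                             outcome_type = "binary")
    eval_idx <- sample.int(n, min(spec$eval_subset, n))
    list(frame = frame,
         truth = list(Y0 = y0, Y1 = y1, ITE = y1 - y0,
                      surface0 = s0, surface1 = s1, eval_idx = eval_idx))
  })
}

#' Simulate the continuous-dose design
#'
#' Arm 1 is the dosed treatment (`T[i,1] = t_i` for treated subjects), arm 2
#' the untreated condition (quantity 1).  The dose is drawn for every
#' subject (inverse-CDF, `t = 1 - log(U)`) but only enters the observable
#' frame for treated subjects; the ground truth retains it for all.
#'
#' @param spec a [continuous_sim_spec()].
#' @return `list(frame, truth)`; `truth` has `Y0`, `Y1`, `ITE`, `dose`, `fx`.
#' @export
simulate_continuous <- function(spec) {
  stopifnot(inherits(spec, "continuous_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    sdn <- noise_sd(spec$noise_value, spec$noise_as_variance)
    x <- rnorm(n)
    dose <- 1 - log(runif(n))
    fx <- 1 / (2 + exp(-20 * (x - 1 / 3)))
    y0 <- 0.3 + fx + rnorm(n, 0, sdn)
    y1 <- 0.3 + fx + 0.1 * dose^2 + rnorm(n, 0, sdn)
    treated <- rbinom(n, 1, spec$assign_prob)
    eta <- ifelse(treated == 1, 1L, 2L)
    Y_f <- ifelse(treated == 1, y1, y0)
    frame <- treatment_frame(matrix(x, ncol = 1), eta, Y_f, K = 2L,
                             dose = ifelse(treated == 1, dose, 1),
                             arm_labels = c("dosed", "untreated"),
                             outcome_type = "continuous")
    list(frame = frame,
         truth = list(Y0 = y0, Y1 = y1, ITE = y1 - y0, dose = dose, fx = fx))
  })
}

#' Export a simulated dataset
#'
#' Writes the observable frame, the ground truth and the full specification
#' (JSON, including the seed) to a directory.
#'
#' @param sim result of [simulate_binary()] or [simulate_continuous()].
#' @param spec the spec that produced it.
#' @param dir output directory (created if needed).
#' @return Paths of the three files, invisibly.
#' @export
write_simulation <- function(sim, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(dir, "frame.csv")
  tp <- file.path(dir, "truth.csv")
  sp <- file.path(dir, "spec.json")
  write_frame(sim$frame, fp)
  tr <- sim$truth
  df <- data.frame(Y0 = tr$Y0, Y1 = tr$Y1, ITE = tr$ITE)
  if (!is.null(tr$dose)) df$dose <- tr$dose
  write.csv(df, tp, row.names = FALSE)
  jsonlite::write_json(c(list(design = class(spec)), unclass(spec)), sp,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(frame = fp, truth = tp, spec = sp))
}
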