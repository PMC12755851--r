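#' Load a population configuration profile
#'
#' Reads one of the shipped YAML profiles (`paper_scale`: 360-s frozen
#' noise at 20 kHz, 1000 presynaptic units, 312 neurons; `test_scale`: 20-s
#' trials at 5 kHz for fast runs) and applies overrides. The profiles
#' define the two class archetypes (broad-spiking, strongly adapting,
#' slowly driven "E"; narrow-spiking, weakly adapting, fast-driven "I")
#' and the acquisition settings.
#'
#' @param profile `"paper_scale"`, `"test_scale"`, or a path to a YAML file.
#' @param ... named overrides merged over the profile (e.g.
#'   `n_neurons = 20`, `fn = list(duration = 5000)`).
#' @return object of class `population_config`.
#' @export
population_config <- function(profile = "test_scale", ...) {
  path <- if (file.exists(profile)) profile else
    system.file("extdata", paste0(profile, ".yaml"), package = "ephysclust")
  if (!nzchar(path)) stop("unknown profile: ", profile)
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        merge_into(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  cfg <- merge_into(cfg, dots)
  w <- vapply(cfg$classes, function(cl) cl$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-6) stop("class mixture weights must sum to 1")
  class(cfg) <- "population_config"
  cfg
}

#' @export
print.population_config <- function(x, ...) {
  cat(sprintf("<population_config> %s: %d neurons, %d classes, FN %g s @ %g kHz\n",
              x$profile, x$n_neurons, length(x$classes),
              x$fn$duration / 1000, 1 / x$fn$dt))
  invisible(x)
}

rnorm_pos <- function(n, mean, sd, lo = 1e-6) pmax(stats::rnorm(n, mean, sd), lo)

# exponential-decay kernel projected on the rectangular basis (bin midpoints)
exp_kernel_coef <- function(basis, amp, tau) {
  mids <- (basis$edges[-1L] + basis$edges[-length(basis$edges)]) / 2
  amp * exp(-mids / tau)
}

#' Sample a ground-truth GLIF population
#'
#' Allocates neurons to classes deterministically in proportion to the
#' mixture weights (largest-remainder rounding), shuffles the order, and
#' draws each neuron's GLIF parameters from its class archetype
#' (independent truncated normals per component; the adaptation and
#' threshold kernels are exponential decays with per-neuron amplitude).
#'
#' @param config a `population_config`.
#' @param seed master seed; default 1.
#' @return object of class `ground_truth`: data.frame `table` (cell id,
#'   class label, per-neuron seed) and list `params` of `glif_params`.
#' @export
sample_population <- function(config, seed = 1L) {
  stopifnot(inherits(config, "population_config"))
  set.seed(seed)
  n <- config$n_neurons
  w <- vapply(config$classes, function(cl) cl$weight, numeric(1))
  base <- floor(w * n)
  rem <- w * n - base
  extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
  counts <- base
  counts[extra] <- counts[extra] + 1L
  cls_idx <- sample(rep.int(seq_along(config$classes), counts))
  kb <- kernel_basis(K = config$kernels$n_basis,
                     support = config$kernels$support,
                     first_edge = config$kernels$first_edge)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- config$classes[[cls_idx[i]]]
    p <- cl$params
    tmpl <- cl$template
    wf <- max(stats::rnorm(1, 1, tmpl$width_sd_frac), 0.5)
    params[[i]] <- glif_params(
      C = rnorm_pos(1, p$C$mean, p$C$sd),
      g_L = rnorm_pos(1, p$g_L$mean, p$g_L$sd),
      E_L = stats::rnorm(1, p$E_L$mean, p$E_L$sd),
      V_reset = stats::rnorm(1, p$V_reset$mean, p$V_reset$sd),
      VT_star = stats::rnorm(1, p$VT_star$mean, p$VT_star$sd),
      delta_V = rnorm_pos(1, p$delta_V$mean, p$delta_V$sd),
      t_ref = 4,
      eta_basis = kb,
      eta_coef = exp_kernel_coef(kb, rnorm_pos(1, cl$eta$amp$mean,
                                               cl$eta$amp$sd),
                                 cl$eta$tau),
      gamma_basis = kb,
      gamma_coef = exp_kernel_coef(kb, rnorm_pos(1, cl$gamma$amp$mean,
                                                 cl$gamma$amp$sd),
                                   cl$gamma$tau),
      template = spike_template(peak = tmpl$peak,
                                rise_ms = tmpl$rise_ms * wf,
                                fall_ms = tmpl$fall_ms * wf))
  }
  labels <- vapply(config$classes, function(cl) cl$label,
                   character(1))[cls_idx]
  out <- list(table = data.frame(cell_id = seq_len(n), class = labels,
                                 seed = seeds),
              params = params, config = config, seed = seed)
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", nrow(x$table), "neurons:",
      paste(sprintf("%s=%d", names(table(x$table$class)),
                    table(x$table$class)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate paired FN and SH recordings for a ground-truth population
#'
#' For each neuron: one frozen-noise trial driven by a presynaptic
#' population seeded by the cell id (class-appropriate hidden-state time
#' constant) and one step-and-hold sweep set. Ground-truth class labels
#' travel in the recording metadata.
#'
#' @param truth a `ground_truth`.
#' @param protocols subset of `c("FN", "SH")` to generate.
#' @param progress print a dot per neuron.
#' @return object of class `recording_set`: lists `fn` (one `recording`
#'   per neuron) and `sh` (one sweep list per neuron), plus `truth`.
#' @export
generate_dataset <- function(truth, protocols = c("FN", "SH"),
                             progress = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  n <- nrow(truth$table)
  fn <- if ("FN" %in% protocols) vector("list", n) else NULL
  sh <- if ("SH" %in% protocols) vector("list", n) else NULL
  sh_proto <- generate_sh_protocol(cfg$sh$step_min, cfg$sh$step_max,
                                   cfg$sh$n_steps, cfg$sh$step_duration,
                                   cfg$sh$holding_potential, cfg$fn$dt,
                                   cfg$sh$pad_pre, cfg$sh$pad_post)
  cls_by_label <- stats::setNames(cfg$classes,
                                  vapply(cfg$classes, `[[`, "", "label"))
  for (i in seq_len(n)) {
    p <- truth$params[[i]]
    cl <- cls_by_label[[truth$table$class[i]]]
    sd_i <- truth$table$seed[i]
    meta <- list(cell_id = truth$table$cell_id[i],
                 class = truth$table$class[i])
    if (!is.null(fn)) {
      pop <- presynaptic_population(cfg$fn$n_units,
                                    kernel_tau = cfg$fn$kernel_tau,
                                    seed = sd_i)
      hid <- generate_hidden_state(cl$tau_fn, cfg$fn$duration, cfg$fn$dt,
                                   seed = sd_i + 1L)
      cur <- generate_fn_current(pop, hid, baseline = cl$baseline,
                                 target_sd = cfg$fn$target_sd,
                                 seed = sd_i + 2L)
      fn[[i]] <- simulate_glif(p, cur, seed = sd_i + 3L, meta = meta)
    }
    if (!is.null(sh)) {
      sh[[i]] <- lapply(seq_along(sh_proto), function(j)
        simulate_glif(p, sh_proto[[j]], seed = sd_i + 10L + j,
                      V0 = cfg$sh$holding_potential,
                      meta = c(meta, sh_proto[[j]]$meta)))
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out <- list(fn = fn, sh = sh, truth = truth)
  class(out) <- "recording_set"
  out
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set> %d neurons (FN: %s, SH: %s)\n",
              nrow(x$truth$table),
              if (is.null(x$fn)) "no" else "yes",
              if (is.null(x$sh)) "no" else "yes"))
  invisible(x)
}

#' Generate data from the shared/private factor model
#'
#' Draws `z`, `x_m` and `Y_m` directly from the MCFA generative model with
#' loadings constructed to hit a specified per-feature variance split:
#' every feature of set m has shared fraction `split[m, 1]`, private
#' fraction `split[m, 2]` and residual fraction `split[m, 3]` (features
#' then have unit total variance in expectation).
#'
#' @param N number of samples (neurons).
#' @param p_list feature dimension per set.
#' @param d shared dimension.
#' @param k_list private dimension per set.
#' @param split matrix (sets x 3) of shared/private/residual fractions, or
#'   a single length-3 vector recycled; rows must sum to 1.
#' @param seed integer seed.
#' @return list with `Y` (list of `attribute_set` matrices) and `truth`
#'   (the generating `W`, `L`, `psi`, `z`, `x`).
#' @export
generate_mcfa_testdata <- function(N, p_list, d = 2L, k_list = 2L,
                                   split = c(0.6, 0.3, 0.1), seed = 1L) {
  M <- length(p_list)
  if (is.null(dim(split))) split <- matrix(split, M, 3L, byrow = TRUE)
  stopifnot(nrow(split) == M, all(abs(rowSums(split) - 1) < 1e-8))
  if (length(k_list) == 1L) k_list <- rep(k_list, M)
  set.seed(seed)
  z <- matrix(stats::rnorm(N * d), N, d)
  W <- L <- psi <- x <- Y <- vector("list", M)
  for (m in seq_len(M)) {
    p <- p_list[m]; k <- k_list[m]
    Wm <- matrix(stats::rnorm(p * d), p, d)
    Wm <- Wm / sqrt(rowSums(Wm^2)) * sqrt(split[m, 1L])
    if (k > 0L) {
      Lm <- matrix(stats::rnorm(p * k), p, k)
      Lm <- Lm / sqrt(rowSums(Lm^2)) * sqrt(split[m, 2L])
    } else Lm <- matrix(0, p, 0L)
    psim <- rep(split[m, 3L], p)
    xm <- matrix(stats::rnorm(N * k), N, k)
    eps <- matrix(stats::rnorm(N * p), N, p) %*% diag(sqrt(psim), p)
    Y[[m]] <- attribute_set(z %*% t(Wm) +
                              (if (k > 0L) xm %*% t(Lm) else 0) + eps,
                            name = paste0("set", m))
    W[[m]] <- Wm; L[[m]] <- Lm; psi[[m]] <- psim; x[[m]] <- xm
  }
  list(Y = Y, truth = list(W = W, L = L, psi = psi, z = z, x = x,
                           split = split))
}
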