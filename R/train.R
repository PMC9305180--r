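#' Trainable-column presets for scenario families
#'
#' Maps a scenario preset to the set of schedule columns that are
#' optimized. Slow-exchanging single-pool scenarios tune only the
#' saturation power; the spectrally broad semisolid (MT) scenario adds
#' the saturation offset; the creatine-phosphate scenario tunes power and
#' both timing parameters; the amine scenario tunes all five.
#'
#' @param preset One of `"b1_only"` (aliases `"iohexol"`, `"bsa_amide"`,
#'   `"bsa_amine"`, `"bsa_rnoe"`, `"invivo_amide"`), `"mt"` (alias
#'   `"invivo_mt"`), `"pcr"`, `"l_arginine"` (alias `"full"`).
#' @return Character vector of trainable schedule column names.
#' @export
optimization_mode <- function(preset) {
  modes <- list(
    b1_only = "omega1_uT",
    mt = c("omega1_uT", "wrf_ppm"),
    pcr = c("omega1_uT", "tsat_s", "trec_s"),
    l_arginine = SCHED_COLS)
  alias <- c(iohexol = "b1_only", bsa_amide = "b1_only",
             bsa_amine = "b1_only", bsa_rnoe = "b1_only",
             invivo_amide = "b1_only", invivo_mt = "mt", full = "l_arginine")
  key <- if (preset %in% names(alias)) alias[[preset]] else preset
  if (!key %in% names(modes))
    abort(paste0("unknown optimization preset: ", preset))
  modes[[key]]
}

target_names <- function(config) {
  tn <- intersect(c("fb", "kb", "fc", "kc"), names(config$ranges))
  if (length(tn) != 2)
    abort("training requires exactly two exchange-parameter ranges (fb/kb or fc/kc)")
  tn
}

target_matrix <- function(config, params) {
  tn <- target_names(config)
  vapply(tn, function(nm) scale_targets(params[[nm]], config$ranges[[nm]]),
         numeric(nrow(params)))
}

# One joint gradient step on a prepared batch. `sm` is the raw 5-column
# schedule matrix; returns updated pieces plus the batch loss.
step_core <- function(sm, trainable, bounds, net, pool_batch, targets,
                      config, state) {
  N <- nrow(sm)
  M <- nrow(pool_batch)
  gcols <- SCHED_COLS %in% trainable
  want_jac <- any(gcols)
  sims <- sim_batch_cpp(pool_batch, n_pools(config$pools), sm,
                        config$field$b0, want_jac, gcols)
  S <- sims$signals + if (config$noise_sigma > 0)
    matrix(rnorm(M * N, 0, config$noise_sigma), M, N) else 0
  nrm <- sqrt(rowSums(S^2))
  if (any(nrm == 0)) abort("zero-norm trajectory in training batch")
  X <- S / nrm
  fwd <- net_forward_raw(net, X)
  err <- fwd$Y - targets
  loss <- mean(err^2)
  if (!is.finite(loss))
    abort(paste0("non-finite training loss (schedule range ",
                 paste(range(sm), collapse = " .. "), ")"))
  dY <- 2 * err / length(err)
  bwd <- net_backward(net, fwd, dY)
  # chain through two-norm normalization back to raw signals
  dS <- (bwd$dX - X * rowSums(X * bwd$dX)) / nrm

  upd <- rmsprop_update(net[c("W1", "b1", "W2", "b2", "W3", "b3")],
                        bwd$grads, state$v_net, config$training$lr_net)
  net[names(upd$params)] <- upd$params
  state$v_net <- upd$state

  if (want_jac) {
    J <- sims$jacobian                    # N x K x M
    K <- dim(J)[2]
    tdL <- t(dS)                          # N x M
    g <- vapply(seq_len(K), function(k) sum(tdL * J[, k, ]), numeric(1))
    tr_cols <- SCHED_COLS[gcols]
    gsched <- setNames(lapply(seq_along(tr_cols),
                              function(s) g[(s - 1) * N + seq_len(N)]),
                       tr_cols)
    cur <- setNames(lapply(tr_cols, function(cn) sm[, cn]), tr_cols)
    upd <- rmsprop_update(cur, gsched, state$v_sched,
                          config$training$lr_schedule)
    state$v_sched <- upd$state
    for (cn in tr_cols) {
      b <- bounds[[cn]]
      sm[, cn] <- pmin(pmax(upd$params[[cn]], b[1]), b[2])
    }
  }
  list(loss = loss, sm = sm, net = net, state = state)
}

new_train_state <- function(net, sm, trainable) {
  list(v_net = rmsprop_init(net[c("W1", "b1", "W2", "b2", "W3", "b3")]),
       v_sched = rmsprop_init(
         setNames(lapply(trainable, function(cn) sm[, cn]), trainable)))
}

#' Single joint optimization step
#'
#' Simulates the batch under the current schedule, injects noise,
#' normalizes, runs the reconstruction network, and takes one RMSprop
#' step on both the network weights and the trainable schedule columns
#' (projected back into their box bounds). Gradients through the physics
#' are exact (matrix-exponential Frechet derivatives), not numerical.
#'
#' @param schedule An [acq_schedule()].
#' @param net A [recon_net()].
#' @param params Batch tibble of tissue parameters (rows <= configured
#'   batch size).
#' @param config A [scenario_config()].
#' @param state Optimizer state from a previous call (or `NULL`).
#' @return List with `loss`, updated `schedule`, `net` and `state`.
#' @export
training_step <- function(schedule, net, params, config, state = NULL) {
  stopifnot(inherits(schedule, "acq_schedule"), inherits(net, "recon_net"),
            inherits(config, "scenario_config"))
  if (nrow(params) > config$training$batch_size)
    abort("batch larger than configured batch size")
  sm <- sched_matrix(schedule)
  trainable <- sched_trainable(schedule)
  bounds <- sched_bounds(schedule)
  if (is.null(state)) state <- new_train_state(net, sm, trainable)
  pm <- pool_param_matrix(params, config$pools)
  targets <- target_matrix(config, params)
  res <- step_core(sm, trainable, bounds, net, pm$mat, targets, config, state)
  out_sched <- acq_schedule(res$sm[, 1], res$sm[, 2], res$sm[, 3],
                            res$sm[, 4], res$sm[, 5],
                            trainable = trainable, bounds = bounds)
  list(loss = res$loss, schedule = out_sched, net = res$net,
       state = res$state)
}

#' Jointly optimize the acquisition schedule and reconstruction network
#'
#' Stochastic gradient descent (RMSprop, two learning rates: one for the
#' schedule parameters, one for the network weights) through the
#' differentiable spin physics. Each epoch shuffles a fixed training set
#' of uniformly drawn tissue-parameter tuples, redraws the additive noise
#' per batch, and evaluates the loss on a disjoint development set with a
#' fixed noise draw (so the development curve is comparable across epochs
#' and flags overfitting).
#'
#' @param config A [scenario_config()].
#' @param init Schedule initialization mode (`"random"` draws trainable
#'   columns uniformly within bounds, `"fixed"` uses configured values).
#' @param seed Integer seed governing every random draw (defaults to the
#'   configured scenario seed).
#' @param verbose Print per-epoch losses.
#' @return An object of class `cest_fit`: optimized `schedule`, trained
#'   `net`, per-epoch `report` tibble (with schedule snapshots), `seed`,
#'   `config_hash` and elapsed wall time.
#' @export
train_system <- function(config, init = c("random", "fixed"),
                         seed = config$seed, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  init <- match.arg(init)
  t0 <- proc.time()[["elapsed"]]
  set.seed(seed)
  schedule <- init_schedule(config, mode = init)
  tn <- target_names(config)
  net <- recon_net(config$n_images, scale = config$ranges[tn])

  tr <- config$training
  train_params <- sample_params(config, tr$n_train)
  dev_params <- sample_params(config, tr$n_dev)
  pm_train <- pool_param_matrix(train_params, config$pools)
  pm_dev <- pool_param_matrix(dev_params, config$pools)
  tgt_train <- target_matrix(config, train_params)
  tgt_dev <- target_matrix(config, dev_params)
  dev_noise <- matrix(rnorm(tr$n_dev * config$n_images, 0,
                            config$noise_sigma), tr$n_dev)

  sm <- sched_matrix(schedule)
  trainable <- sched_trainable(schedule)
  bounds <- sched_bounds(schedule)
  state <- new_train_state(net, sm, trainable)

  # refresh input-standardization constants from the current schedule
  std_idx <- seq_len(min(2048L, tr$n_train))
  refresh_standardization <- function(net, sm) {
    sims <- sim_batch_cpp(pm_train$mat[std_idx, , drop = FALSE],
                          pm_train$npools, sm, config$field$b0, FALSE,
                          rep(FALSE, 5))
    S <- sims$signals
    if (config$noise_sigma > 0)
      S <- S + matrix(rnorm(length(S), 0, config$noise_sigma), nrow(S))
    set_input_standardization(net, normalize_trajectory(S))
  }
  net <- refresh_standardization(net, sm)

  dev_loss_of <- function(sm, net) {
    sims <- sim_batch_cpp(pm_dev$mat, pm_dev$npools, sm, config$field$b0,
                          FALSE, rep(FALSE, 5))
    X <- normalize_trajectory(sims$signals + dev_noise)
    mean((net_forward_raw(net, X)$Y - tgt_dev)^2)
  }

  report <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                           dev_loss = numeric(), schedule = list())
  dev0 <- NULL
  n_diverged <- 0
  best <- list(dev = Inf, sm = sm, net = net)
  epochs <- tr$epochs
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      if (ep > 1) net <- refresh_standardization(net, sm)
      ord <- sample.int(tr$n_train)
      nb <- ceiling(tr$n_train / tr$batch_size)
      losses <- numeric(nb)
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1) * tr$batch_size + 1):min(b * tr$batch_size,
                                                     tr$n_train)]
        res <- step_core(sm, trainable, bounds, net, pm_train$mat[idx, ,
                         drop = FALSE], tgt_train[idx, , drop = FALSE],
                         config, state)
        sm <- res$sm; net <- res$net; state <- res$state
        losses[b] <- res$loss
      }
      dl <- dev_loss_of(sm, net)
      if (dl < best$dev) best <- list(dev = dl, sm = sm, net = net)
      if (is.null(dev0)) dev0 <- dl
      n_diverged <- if (dl > 10 * dev0) n_diverged + 1 else 0
      report <- dplyr::bind_rows(report, tibble::tibble(
        epoch = ep, train_loss = mean(losses), dev_loss = dl,
        schedule = list(sm)))
      if (verbose)
        message(sprintf("epoch %3d  train %.3e  dev %.3e", ep,
                        mean(losses), dl))
      if (n_diverged >= 5)
        rlang::abort("training diverged (dev loss > 10x initial for 5 epochs)",
                     class = "cestopt_divergence", report = report)
    }
  }
  # return the epoch with the lowest development loss (the dev set exists
  # to guard against over- and under-shooting late in training)
  if (is.finite(best$dev)) { sm <- best$sm; net <- best$net }
  out_sched <- acq_schedule(sm[, 1], sm[, 2], sm[, 3], sm[, 4], sm[, 5],
                            trainable = trainable, bounds = bounds)
  structure(list(schedule = out_sched, net = net, report = report,
                 config = config, seed = seed,
                 config_hash = rlang::hash(config),
                 elapsed_s = proc.time()[["elapsed"]] - t0),
            class = "cest_fit")
}

#' @export
print.cest_fit <- function(x, ...) {
  cat(sprintf("<cest_fit: %d epochs, %.1f s; final dev loss %s>\n",
              nrow(x$report), x$elapsed_s,
              if (nrow(x$report)) format(x$report$dev_loss[nrow(x$report)],
                                         digits = 3) else "NA"))
  invisible(x)
}

#' @describeIn train_system Per-epoch training and development losses.
#' @param x A `cest_fit`.
#' @param ... Unused.
#' @export
tidy.cest_fit <- function(x, ...) {
  x$report[, c("epoch", "train_loss", "dev_loss")]
}

#' @describeIn train_system One-row summary of the fitted system.
#' @export
glance.cest_fit <- function(x, ...) {
  n <- nrow(x$report)
  tibble::tibble(
    epochs = n,
    train_loss = if (n) x$report$train_loss[n] else NA_real_,
    dev_loss = if (n) x$report$dev_loss[n] else NA_real_,
    acquisition_time_s = acquisition_time(x$schedule),
    elapsed_s = x$elapsed_s, seed = x$seed)
}

#' @describeIn train_system Training / development loss curves.
#' @param object A `cest_fit`.
#' @export
autoplot.cest_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), -"epoch",
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "mean squared error (scaled units)")
}
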