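#' Training configuration
#'
#' Adam with the mean absolute error loss for the density network and mean
#' squared error for the parameter network, mini-batches of one sample,
#' random integer translation augmentation applied identically to all input
#' channels (and to the target, for the density network), and early
#' stopping on the held-out-subject loss.
#'
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param max_epochs hard epoch cap.
#' @param patience stop after this many epochs without test-loss
#'   improvement.
#' @param shift maximum augmentation shift in voxels per non-singleton
#'   axis.
#' @param seed RNG seed controlling initialization order, shuffling and
#'   augmentation draws.
#' @return list of class \code{training_config}.
#' @export
training_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-6, max_epochs = 1000, patience = 100,
                            shift = 15, seed = 0) {
  if (patience < 1) stop("patience must be >= 1")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 max_epochs = max_epochs, patience = patience,
                 shift = as.integer(shift), seed = seed),
            class = "training_config")
}

# integer-shift an (x, y, z, c) array with zero fill, same shift per channel
shift_array <- function(x, shift) {
  d <- dim(x)
  if (all(shift == 0)) return(x)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    s <- shift[i]
    if (abs(s) >= d[i]) return(out)
    src[[i]] <- if (s >= 0) 1:(d[i] - s) else (1 - s):d[i]
    dst[[i]] <- if (s >= 0) (1 + s):d[i] else 1:(d[i] + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]], ] <-
    x[src[[1]], src[[2]], src[[3]], , drop = FALSE]
  out
}

# ---- sample assembly --------------------------------------------------------

region_channel <- function(region) {
  v <- array(0, dim = region$dim)
  v[region$mask] <- 1
  v
}

#' Assemble network input channels for one tumor record
#'
#' Density network inputs are the core and edema regions at t2 plus the 6
#' unit-tensor components (8 channels); parameter network inputs add the
#' edema region at t1 (9 channels) and carry the imaging interval dt2 in
#' days as a scalar side input.
#'
#' @param record a \code{\link{synthesize_tumor}} record with stored
#'   regions.
#' @param unit_tensor the subject's unit tumor \code{\link{tensor_field}}.
#' @param task \code{"density"} or \code{"parameters"}.
#' @param ranges a \code{\link{sampling_ranges}} (target standardization).
#' @return list with \code{x} (input array), and for the density task
#'   \code{target} (density array), for the parameter task \code{dt2} and
#'   standardized \code{target}.
#' @export
network_sample <- function(record, unit_tensor,
                           task = c("parameters", "density"),
                           ranges = sampling_ranges()) {
  task <- match.arg(task)
  dims <- record$snapshots[[2]]$dim
  tens <- tensor_array(unit_tensor)
  if (task == "density") {
    x <- array(0, dim = c(dims, 8))
    x[, , , 1] <- region_channel(record$regions$core_t2)
    x[, , , 2] <- region_channel(record$regions$edema_t2)
    x[, , , 3:8] <- tens
    target <- array(record$snapshots[[2]]$values, dim = c(dims, 1))
    list(x = x, target = target)
  } else {
    x <- array(0, dim = c(dims, 9))
    x[, , , 1] <- region_channel(record$regions$core_t2)
    x[, , , 2] <- region_channel(record$regions$edema_t2)
    x[, , , 3] <- region_channel(record$regions$edema_t1)
    x[, , , 4:9] <- tens
    z <- standardize_targets(record$parameters$lambda, record$parameters$v,
                             ranges)
    list(x = x, dt2 = record$parameters$dt2, target = as.vector(z))
  }
}

# ---- Adam over nested gradient structures ----------------------------------

adam_init <- function(grads) rapply(grads, function(g) g * 0, how = "replace")

flatten_grads <- function(g) {
  out <- list()
  walk <- function(x, path) {
    if (is.list(x)) for (i in seq_along(x)) walk(x[[i]], c(path, i))
    else out[[length(out) + 1]] <<- list(path = path, value = x)
  }
  walk(g, integer(0))
  out
}

# applies Adam in place on parallel nested lists (params, grads, m, v)
adam_step <- function(state, grads, config) {
  state$t <- state$t + 1
  bc1 <- 1 - config$beta1^state$t
  bc2 <- 1 - config$beta2^state$t
  upd <- function(m, v, g) {
    m <- config$beta1 * m + (1 - config$beta1) * g
    v <- config$beta2 * v + (1 - config$beta2) * g * g
    list(m = m, v = v,
         delta = config$lr * (m / bc1) / (sqrt(v / bc2) + config$eps))
  }
  walk <- function(m, v, g) {
    if (is.list(g)) {
      for (i in seq_along(g)) {
        r <- walk(m[[i]], v[[i]], g[[i]])
        m[[i]] <- r$m; v[[i]] <- r$v; g[[i]] <- r$delta
      }
      return(list(m = m, v = v, delta = g))
    }
    upd(m, v, g)
  }
  r <- walk(state$m, state$v, grads)
  state$m <- r$m; state$v <- r$v
  list(state = state, delta = r$delta)
}

apply_delta_parameter <- function(model, delta) {
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$w <- model$layers[[i]]$w - delta[[i]]$dw
    model$layers[[i]]$b <- model$layers[[i]]$b - delta[[i]]$db
  }
  model
}

apply_delta_density <- function(model, delta) {
  for (b in seq_along(model$down))
    for (l in 1:3) {
      model$down[[b]][[l]]$w <- model$down[[b]][[l]]$w - delta$down[[b]][[l]]$dw
      model$down[[b]][[l]]$b <- model$down[[b]][[l]]$b - delta$down[[b]][[l]]$db
    }
  for (b in seq_along(model$up))
    for (l in 1:3) {
      model$up[[b]][[l]]$w <- model$up[[b]][[l]]$w - delta$up[[b]][[l]]$dw
      model$up[[b]][[l]]$b <- model$up[[b]][[l]]$b - delta$up[[b]][[l]]$db
    }
  for (l in 1:3) {
    model$out[[l]]$w <- model$out[[l]]$w - delta$out[[l]]$dw
    model$out[[l]]$b <- model$out[[l]]$b - delta$out[[l]]$db
  }
  model
}

# ---- training ---------------------------------------------------------------

#' Train a network on a synthetic tumor dataset
#'
#' Runs Adam with batch size 1 over the training records, evaluating the
#' loss on the held-out-subject test records after every epoch, keeping the
#' weights with the best test loss and stopping early when it has not
#' improved for \code{config$patience} epochs. Augmentation draws one
#' integer shift triple per training sample per epoch, applied identically
#' to every input channel (and the target for the density task).
#'
#' @param model a \code{\link{build_parameter_network}} or
#'   \code{\link{build_density_network}} model.
#' @param dataset a \code{\link{build_dataset}} result.
#' @param unit_tensors named list mapping subject id to its unit tensor.
#' @param config a \code{\link{training_config}}.
#' @param verbose print per-epoch losses.
#' @return list with \code{model} (best weights), \code{history}
#'   (data.frame of train/test loss per epoch) and \code{best_epoch}.
#' @export
train_network <- function(model, dataset, unit_tensors,
                          config = training_config(), verbose = FALSE) {
  task <- if (inherits(model, "parameter_network")) "parameters" else "density"
  if (length(dataset$train_idx) == 0 || length(dataset$test_idx) == 0)
    stop("empty train or test split")
  samples <- lapply(dataset$records, function(r)
    network_sample(r, unit_tensors[[r$subject_id]], task, dataset$ranges))
  d3 <- dim(samples[[1]]$x)[1:3]
  shifts_max <- ifelse(d3 > 1, config$shift, 0L)

  adam_env$state <- NULL
  with_seed(config$seed, {
    best <- list(loss = Inf, model = model, epoch = 0)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       test_loss = numeric(0))
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(dataset$train_idx)
      train_loss <- 0
      for (idx in ord) {
        smp <- samples[[idx]]
        sh <- vapply(1:3, function(i)
          if (shifts_max[i] > 0)
            sample(-shifts_max[i]:shifts_max[i], 1) else 0L, integer(1))
        x <- shift_array(smp$x, sh)
        if (task == "parameters") {
          fwd <- forward_parameter_network(model, x, smp$dt2, keep_cache = TRUE)
          err <- fwd$y - smp$target
          train_loss <- train_loss + mean(err^2)
          grads <- backward_parameter_network(model, fwd, 2 * err / length(err))
          st <- adam_step(adam_state(model, grads), grads, config)
          adam_env$state <- st$state
          model <- apply_delta_parameter(model, st$delta)
        } else {
          tgt <- shift_array(smp$target, sh)
          fwd <- forward_density_network(model, x, keep_cache = TRUE)
          err <- fwd$y - tgt
          train_loss <- train_loss + mean(abs(err))
          dy <- sign(err) / length(err)
          dim(dy) <- dim(err)
          grads <- backward_density_network(model, fwd, dy)
          st <- adam_step(adam_state(model, grads), grads, config)
          adam_env$state <- st$state
          model <- apply_delta_density(model, st$delta)
        }
      }
      train_loss <- train_loss / length(ord)
      test_loss <- evaluate_loss(model, samples, dataset$test_idx, task)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                     test_loss = test_loss))
      if (verbose)
        message(sprintf("epoch %d: train %.5f test %.5f", epoch, train_loss,
                        test_loss))
      if (test_loss < best$loss)
        best <- list(loss = test_loss, model = model, epoch = epoch)
      if (epoch - best$epoch >= config$patience) break
    }
    adam_env$state <- NULL
    list(model = best$model, history = hist, best_epoch = best$epoch)
  })
}

# per-training-run Adam state, keyed off the calling train_network invocation
adam_env <- new.env(parent = emptyenv())

adam_state <- function(model, grads) {
  if (is.null(adam_env$state))
    adam_env$state <- list(t = 0, m = adam_init(grads), v = adam_init(grads))
  adam_env$state
}

evaluate_loss <- function(model, samples, idx, task) {
  total <- 0
  for (i in idx) {
    smp <- samples[[i]]
    if (task == "parameters") {
      fwd <- forward_parameter_network(model, smp$x, smp$dt2)
      total <- total + mean((fwd$y - smp$target)^2)
    } else {
      fwd <- forward_density_network(model, smp$x)
      total <- total + mean(abs(fwd$y - smp$target))
    }
  }
  total / length(idx)
}

#' Predict growth parameters for a tumor record
#'
#' Runs the trained parameter network on a record's contour and tensor
#' channels and destandardizes the outputs into an estimate of
#' (lambda, v), with dwhite and rho derived from them.
#'
#' @param object a trained \code{parameter_network}.
#' @param record a tumor record with stored regions.
#' @param unit_tensor the subject's unit tensor.
#' @param ranges a \code{\link{sampling_ranges}}.
#' @param ... unused.
#' @return a \code{\link{glioma_estimate}}.
#' @export
predict.parameter_network <- function(object, record, unit_tensor,
                                      ranges = sampling_ranges(), ...) {
  smp <- network_sample(record, unit_tensor, "parameters", ranges)
  fwd <- forward_parameter_network(object, smp$x, smp$dt2)
  lv <- destandardize_targets(fwd$y, ranges)
  glioma_estimate(lv[1, "lambda"], lv[1, "v"], method = "network")
}

#' Predict a density field from contour inputs
#'
#' @param object a trained \code{density_network}.
#' @param record a tumor record with stored regions.
#' @param unit_tensor the subject's unit tensor.
#' @param ... unused.
#' @return a \code{\link{density_field}} at the record's t2 (raw network
#'   output; apply \code{\link{postprocess_density}} before forecasting).
#' @export
predict.density_network <- function(object, record, unit_tensor, ...) {
  smp <- network_sample(record, unit_tensor, "density")
  fwd <- forward_density_network(object, smp$x)
  v <- fwd$y
  dim(v) <- dim(v)[1:3]
  f <- record$snapshots[[2]]
  structure(list(values = v, spacing = f$spacing, time = f$time,
                 dim = dim(v)), class = "density_field")
}
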