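# --- training --------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the published recipe: Adam with moments (0.9, 0.999),
#' initial learning rate 2e-5 under cosine annealing restarting every 20
#' epochs, batch size 8. The full schedule runs 200 epochs; the tiny
#' desk-scale default is 5.
#'
#' @param batch_size samples per optimization step
#' @param beta1,beta2 Adam moment decay rates
#' @param lr initial learning rate
#' @param restart_period cosine-annealing restart period (epochs)
#' @param epochs training epochs
#' @param seed master seed controlling all stochastic steps
#' @return a `train_config` list
#' @export
train_config <- function(batch_size = 8L, beta1 = 0.9, beta2 = 0.999,
                         lr = 2e-5, restart_period = 20L, epochs = 5L,
                         seed = 7L) {
  stopifnot(batch_size >= 1, lr > 0, epochs >= 0,
            restart_period >= 1)
  structure(list(batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, lr = lr,
                 restart_period = as.integer(restart_period),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

# recursively wrap every numeric leaf of a parameter list in ag_param nodes;
# returns list(tree = wrapped structure, leaves = named flat list of nodes)
wrap_params <- function(params) {
  leaves <- list()
  rec <- function(p, path) {
    if (is.list(p)) {
      nm <- names(p)
      out <- vector("list", length(p))
      names(out) <- nm
      for (i in seq_along(p)) {
        key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        out[[i]] <- rec(p[[i]], paste0(path, "/", key))
      }
      out
    } else {
      n <- ag_param(p)
      leaves[[path]] <<- n
      n
    }
  }
  tree <- rec(params, "")
  list(tree = tree, leaves = leaves)
}

# read plain values back out of a wrapped tree
unwrap_params <- function(tree) {
  if (is.list(tree)) lapply(tree, unwrap_params) else ag_value(tree)
}

adam_init <- function(leaves) {
  lapply(leaves, function(n) {
    v <- ag_value(n)
    list(m = v * 0, v = v * 0)
  })
}

adam_step <- function(values, grads, state, t, lr, beta1, beta2, eps = 1e-8) {
  for (k in names(values)) {
    g <- grads[[k]]
    if (is.null(g)) next
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[k]] <- st
    mh <- st$m / (1 - beta1^t)
    vh <- st$v / (1 - beta2^t)
    values[[k]] <- values[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(values = values, state = state)
}

cosine_lr <- function(epoch, lr0, period) {
  phase <- ((epoch - 1) %% period) / period
  lr0 * 0.5 * (1 + cos(pi * phase))
}

# flatten/unflatten plain parameter trees using the same path keys as
# wrap_params, so Adam state aligns across steps and resumes
flatten_params <- function(params) {
  out <- list()
  rec <- function(p, path) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        rec(p[[i]], paste0(path, "/", key))
      }
    } else out[[path]] <<- p
  }
  rec(params, "")
  out
}

unflatten_params <- function(flat, template) {
  rec <- function(p, path) {
    if (is.list(p)) {
      nm <- names(p)
      out <- vector("list", length(p)); names(out) <- nm
      for (i in seq_along(p)) {
        key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        out[[i]] <- rec(p[[i]], paste0(path, "/", key))
      }
      out
    } else flat[[path]]
  }
  rec(template, "")
}

# deepest MS-SSIM pyramid that fits the image, capped at 5
msssim_levels_for <- function(side) {
  max(1L, min(5L, floor(log2(side / 11)) + 1L))
}

#' Train the restoration model on paired synthetic samples
#'
#' Jointly optimizes the CALW front end and the degradation-guided network
#' end to end under the physics-constrained composite loss. All stochastic
#' steps (epoch shuffling) derive from the master seed, so runs are
#' reproducible and a run resumed from a checkpoint follows the identical
#' trajectory of an uninterrupted run.
#'
#' @param samples list of [degrade()] samples (the training set)
#' @param net_config a [network_config()]
#' @param cfg a [train_config()]
#' @param weights a [loss_weights()]
#' @param val_samples optional held-out samples; validation PSNR/SSIM of the
#'   full model is logged per epoch
#' @param checkpoint optional checkpoint to resume from (its parameters,
#'   optimizer state and epoch counter are continued)
#' @return a `psf4d_checkpoint`: list with `params`, `net_config`, `cfg`,
#'   `weights`, `opt_state`, `epochs_done`, and a tibble `log`
#' @export
train_model <- function(samples, net_config = network_config("tiny"),
                        cfg = train_config(), weights = loss_weights(),
                        val_samples = NULL, checkpoint = NULL) {
  stopifnot(length(samples) >= 1)
  if (is.null(checkpoint)) {
    params <- list(calw = calw_init(seed = derive_seed(cfg$seed, "calw")),
                   net = dgnet_init(net_config, seed = derive_seed(cfg$seed, "net")))
    opt_state <- NULL
    t_step <- 0L
    epoch0 <- 0L
    log <- NULL
  } else {
    params <- checkpoint$params
    opt_state <- checkpoint$opt_state
    t_step <- checkpoint$t_step
    epoch0 <- checkpoint$epochs_done
    log <- checkpoint$log
    net_config <- checkpoint$net_config
    weights <- checkpoint$weights
  }
  gt_side <- dim(samples[[1]]$gt_x)[1]
  lv <- msssim_levels_for(gt_side)
  flat <- flatten_params(params)
  if (is.null(opt_state)) opt_state <- lapply(flat, function(v) list(m = v * 0, v = v * 0))
  logs <- if (is.null(log)) list() else list(log)
  last_good <- flat
  aborted <- FALSE
  for (epoch in (epoch0 + 1L):(epoch0 + cfg$epochs)) {
    if (cfg$epochs == 0L || aborted) break
    lr <- cosine_lr(epoch, cfg$lr, cfg$restart_period)
    ord <- with_seed(derive_seed(cfg$seed, paste0("epoch", epoch)),
                     sample.int(length(samples)))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_losses <- c(); ep_break <- c(fid = 0, phys = 0, ssim = 0, tv = 0)
    for (b in batches) {
      params_now <- unflatten_params(flat, params)
      w <- wrap_params(params_now)
      loss_node <- NULL
      bk <- c(fid = 0, phys = 0, ssim = 0, tv = 0)
      for (si in b) {
        s <- samples[[si]]
        kern <- center_kernels(s$psf_set)
        xh <- restore_node(s$input_y, kern, w$tree, net_config)
        psf_c <- if (weights$w_phys > 0)
          calw_corrected_kernels(s$psf_set, w$tree$calw) else s$psf_set
        li <- total_loss(xh, s$gt_x, s$input_y, psf_c, weights,
                         ssim_levels = lv)
        bk <- bk + li$breakdown / length(b)
        loss_node <- if (is.null(loss_node)) li else ag_add(loss_node, li)
      }
      loss_node <- ag_mul(loss_node, 1 / length(b))
      lossv <- ag_value(loss_node)
      if (!is.finite(lossv)) {
        warning("non-finite loss; aborting at last good checkpoint")
        flat <- last_good
        aborted <- TRUE
        break
      }
      ag_backward(loss_node)
      grads <- lapply(w$leaves, function(n) n$grad)
      names(grads) <- names(w$leaves)
      t_step <- t_step + 1L
      upd <- adam_step(flat, grads, opt_state, t_step, lr, cfg$beta1, cfg$beta2)
      flat <- upd$values; opt_state <- upd$state
      last_good <- flat
      ep_losses <- c(ep_losses, lossv)
      ep_break <- ep_break + bk / length(batches)
    }
    val_psnr <- val_ssim <- NA_real_
    if (!is.null(val_samples)) {
      pm <- unflatten_params(flat, params)
      vv <- eval_metrics(val_samples, pm, net_config, mode = "full")
      val_psnr <- mean(vv$psnr); val_ssim <- mean(vv$ssim)
    }
    logs[[length(logs) + 1L]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss = mean(ep_losses),
      fid = ep_break["fid"], phys = ep_break["phys"],
      ssim_term = ep_break["ssim"], tv = ep_break["tv"],
      val_psnr = val_psnr, val_ssim = val_ssim)
  }
  structure(list(params = unflatten_params(flat, params),
                 net_config = net_config, cfg = cfg, weights = weights,
                 opt_state = opt_state, t_step = t_step,
                 epochs_done = epoch0 + cfg$epochs,
                 log = do.call(rbind, logs)),
            class = "psf4d_checkpoint")
}

#' Save / load a training checkpoint
#' @param ckpt a `psf4d_checkpoint`
#' @param path file path
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# per-sample metrics for one restoration mode
eval_metrics <- function(samples, params, net_config, mode) {
  rows <- lapply(samples, function(s) {
    out <- restore_image(s$input_y, s$psf_set, params, net_config, mode = mode)
    tibble::tibble(beta = s$beta, method = mode,
                   psnr = psnr(out, s$gt_x), ssim = ssim(out, s$gt_x))
  })
  do.call(rbind, rows)
}

#' Evaluate restoration quality across magnifications
#'
#' Computes mean PSNR and SSIM per magnification level for the full model,
#' the Wiener-only front end, and the bicubic-upsampled-input baseline.
#'
#' @param samples list of held-out [degrade()] samples
#' @param ckpt a `psf4d_checkpoint` (or a list with `params`/`net_config`)
#' @param out_csv optional path; the table is written as CSV
#' @return tibble with columns `magnification`, `method`, `psnr`, `ssim`, `n`
#' @export
evaluate_model <- function(samples, ckpt, out_csv = NULL) {
  res <- do.call(rbind, lapply(c("full", "wiener", "bicubic"), function(m)
    eval_metrics(samples, ckpt$params, ckpt$net_config, m)))
  agg <- stats::aggregate(cbind(psnr, ssim) ~ beta + method, data = res, FUN = mean)
  n <- stats::aggregate(psnr ~ beta + method, data = res, FUN = length)
  out <- tibble::tibble(magnification = agg$beta, method = agg$method,
                        psnr = agg$psnr, ssim = agg$ssim, n = n$psnr)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
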