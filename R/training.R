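# Three-phase training curriculum, schedules, evaluation and checkpoints.
#
# Phase 1 trains the decoder alone (encoder frozen) with the segmentation
# loss only; phase 2 unfreezes everything and optimizes the full composite
# objective under cosine learning-rate annealing and Gumbel-temperature
# decay; phase 3 ramps the balance weight and enables stochastic gating
# dropout to reinforce expert specialization, with early stopping when the
# utilization-entropy trajectory flattens.

#' Cosine learning-rate schedule with linear warmup
#'
#' Linear warmup to `eta_max` over `warmup` epochs, then
#' `eta(t) = eta_min + 0.5 (eta_max - eta_min)(1 + cos(pi t' / T'))` over
#' the remaining span.
#'
#' @param t current epoch in `[0, T]`.
#' @param T total epochs (> 0).
#' @param eta_max peak learning rate.
#' @param eta_min floor learning rate (default 1e-6).
#' @param warmup warmup epochs.
#' @return Learning rate at `t`.
#' @export
cosine_lr <- function(t, T, eta_max, eta_min = 1e-6, warmup = 0) {
  if (T <= 0) stop("T must be positive")
  stopifnot(t >= 0, t <= T, eta_min < eta_max)
  if (warmup > 0 && t < warmup) return(eta_max * t / warmup)
  span <- T - warmup
  tt <- t - warmup
  eta_min + 0.5 * (eta_max - eta_min) * (1 + cos(pi * tt / span))
}

#' Gumbel temperature schedule
#'
#' Geometric interpolation `tau_t = tau0 * (0.1 / tau0)^(t / T)` from
#' `tau0` at `t = 0` to 0.1 at `t = T`.
#'
#' @param t current epoch, @param T total epochs, @param tau0 start value.
#' @return Temperature at `t`.
#' @export
gumbel_temperature <- function(t, T, tau0 = 1.0) {
  stopifnot(t >= 0, t <= T, tau0 > 0)
  tau0 * (0.1 / tau0)^(t / T)
}

#' Training schedule
#'
#' Reference defaults: 100 epochs, batch 16, encoder learning rate 3e-4,
#' decoder 1e-3, 10 warmup epochs, floor 1e-6, weight decay 1e-2 (1e-4
#' selectable), gradient clipping at norm 1.0, Gumbel temperature annealed
#' 1.0 to 0.1. Phase boundaries default to 20%/70%/10% of the epochs.
#'
#' @param epochs total epochs T.
#' @param batch minibatch size.
#' @param lr_encoder,lr_decoder peak learning rates.
#' @param warmup_epochs linear warmup length.
#' @param eta_min cosine floor.
#' @param weight_decay decoupled weight decay.
#' @param grad_clip global gradient-norm clip.
#' @param tau0,tau_final Gumbel temperature endpoints.
#' @param phase_boundaries integer length-2 `(p1_end, p2_end)` epochs.
#' @param lambda1_ramp multiplier reached by the balance weight at the end
#'   of phase 3.
#' @param gate_dropout_p phase-3 stochastic gating dropout rate.
#' @param early_stop_delta,early_stop_window phase-3 early stop: halt when
#'   utilization entropy changes less than `delta` bits over `window`
#'   epochs.
#' @param seed master seed for shuffling and noise streams.
#' @export
train_schedule <- function(epochs = 100L, batch = 16L, lr_encoder = 3e-4,
                           lr_decoder = 1e-3, warmup_epochs = 10L,
                           eta_min = 1e-6, weight_decay = 1e-2,
                           grad_clip = 1.0, tau0 = 1.0, tau_final = 0.1,
                           phase_boundaries = NULL, lambda1_ramp = 5,
                           gate_dropout_p = 0.1, early_stop_delta = 0.01,
                           early_stop_window = 5L, seed = 1L) {
  if (is.null(phase_boundaries))
    phase_boundaries <- c(max(1L, round(0.2 * epochs)),
                          max(2L, round(0.9 * epochs)))
  # boundaries beyond `epochs` simply mean the later phases are not reached
  stopifnot(eta_min < lr_encoder, eta_min < lr_decoder,
            phase_boundaries[1] < phase_boundaries[2])
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr_encoder = lr_encoder, lr_decoder = lr_decoder,
                 warmup_epochs = as.integer(warmup_epochs),
                 eta_min = eta_min, weight_decay = weight_decay,
                 grad_clip = grad_clip, tau0 = tau0, tau_final = tau_final,
                 phase_boundaries = as.integer(phase_boundaries),
                 lambda1_ramp = lambda1_ramp,
                 gate_dropout_p = gate_dropout_p,
                 early_stop_delta = early_stop_delta,
                 early_stop_window = as.integer(early_stop_window),
                 seed = as.integer(seed)),
            class = "train_schedule")
}

# tape segmentation loss (BCE + soft Dice) against a fixed binary mask
seg_loss_node <- function(y_hat, y, epsilon = 1.0) {
  yv <- as.numeric(y)
  bce <- ad_bce(y_hat, matrix(yv, ncol = 1L))
  inter <- ad_sum(ad_mul(y_hat, matrix(yv, ncol = 1L)))
  dice <- ad_sub(1, ad_div(ad_add(ad_mul(inter, 2), epsilon),
                           ad_add(ad_add(ad_sum(y_hat), sum(yv)), epsilon)))
  ad_add(bce, dice)
}

balance_loss_node <- function(alpha) {
  f <- ad_colmeans_row(alpha)
  mu <- ad_mean(f)
  d <- ad_sub(f, mu)
  ad_mean(ad_mul(d, d))
}

sparsity_loss_node <- function(attn_nodes) {
  out <- NULL
  for (A in attn_nodes) {
    term <- ad_mul(ad_sum(ad_abs(A)), 1 / nrow(A$value))
    out <- if (is.null(out)) term else ad_add(out, term)
  }
  out
}

# negated entropy of the retained attention weights (log base 2); zero
# entries contribute nothing because they multiply the clamped log
diversity_loss_node <- function(attn_nodes) {
  out <- NULL
  for (A in attn_nodes) {
    term <- ad_mul(ad_sum(ad_mul(A, ad_log(A))),
                   1 / (nrow(A$value) * log(2)))
    out <- if (is.null(out)) term else ad_add(out, term)
  }
  ad_mul(out, 1 / length(attn_nodes))
}

routing_entropy_node <- function(alpha) {
  ad_mul(ad_sum(ad_mul(alpha, ad_log(alpha))),
         -1 / (nrow(alpha$value) * log(2)))
}

scene_pair <- function(s) {
  if (inherits(s, "synthetic_scene")) list(image = s$image, mask = s$mask)
  else s
}

#' Train the segmentation model on a set of scenes
#'
#' Runs the three-phase curriculum: decoder-only warm start on the
#' segmentation loss with a frozen encoder, full composite-objective
#' fine-tuning, and a final specialization phase with a ramped balance
#' weight and stochastic gating dropout. All noise streams derive from the
#' schedule seed, so two runs with the same inputs produce identical loss
#' curves.
#'
#' @param model a [build_model()] object.
#' @param scenes list of `synthetic_scene`s or `list(image, mask)` pairs.
#' @param schedule a [train_schedule()].
#' @param weights a [loss_weights()].
#' @param lambda_diversity,lambda_entropy optional weights for the
#'   attention-diversity and routing-entropy terms; both terms are always
#'   computed and logged but enter the objective only when nonzero.
#' @param policy optional [augmentation_policy()] applied per sample.
#' @param val_scenes optional held-out scenes; mean IoU is computed at the
#'   end of training and stored in the checkpoint.
#' @param verbose print one line per epoch.
#' @return A `checkpoint`: trained model, optimizer state, per-epoch
#'   history (loss components, tau, utilization entropy), the epoch
#'   reached, and `best_val_iou` when validation scenes were supplied.
#' @export
train_model <- function(model, scenes, schedule = train_schedule(),
                        weights = loss_weights(), lambda_diversity = 0,
                        lambda_entropy = 0, policy = NULL,
                        val_scenes = NULL, verbose = FALSE) {
  enc_names <- encoder_param_names(model)
  opt <- adamw_init()
  history <- list()
  ent_track <- numeric(0)
  p1 <- schedule$phase_boundaries[1]
  p2 <- schedule$phase_boundaries[2]
  T <- schedule$epochs
  n <- length(scenes)
  stopped_early <- FALSE
  for (epoch in seq_len(T)) {
    phase <- if (epoch <= p1) 1L else if (epoch <= p2) 2L else 3L
    tau <- gumbel_temperature(epoch - 1L, T, schedule$tau0)
    # schedules are evaluated at the epoch midpoint so that the first
    # warmup epoch trains at half the peak rate instead of zero
    lr_enc <- cosine_lr(epoch - 0.5, T, schedule$lr_encoder,
                        schedule$eta_min, schedule$warmup_epochs)
    lr_dec <- cosine_lr(epoch - 0.5, T, schedule$lr_decoder,
                        schedule$eta_min, schedule$warmup_epochs)
    lr_for <- function(nm) if (nm %in% enc_names) lr_enc else lr_dec
    # gate noise anneals linearly to zero by the end of phase 2
    model$gate_noise_scale <- max(0, 1 - (epoch - 1) / p2)
    model$gate_dropout <- if (phase == 3L) schedule$gate_dropout_p else 0
    lam1 <- weights$lambda1 *
      if (phase == 3L && T > p2)
        1 + (schedule$lambda1_ramp - 1) * (epoch - p2) / (T - p2) else 1
    ord <- with_seed(schedule$seed + 7919L * epoch, sample(n))
    ep_loss <- c(seg = 0, balance = 0, sparsity = 0, total = 0)
    ep_aux <- c(diversity = 0, entropy = 0)
    decisions <- list()
    n_batches <- 0L
    for (bstart in seq(1L, n, by = schedule$batch)) {
      bidx <- ord[bstart:min(bstart + schedule$batch - 1L, n)]
      grads <- NULL
      for (i in bidx) {
        sp <- scene_pair(scenes[[i]])
        smp_seed <- (schedule$seed %% 997L) * 1000000L + epoch * 4096L + i
        if (!is.null(policy)) {
          a <- augment(sp$image, sp$mask, policy, seed = smp_seed)
          sp <- list(image = a$image, mask = a$mask)
        }
        m <- model
        m$config$gate_noise_sigma <-
          model$config$gate_noise_sigma * model$gate_noise_scale
        fw <- model_forward_node(m, sp$image, mode = "train", tau = tau,
                                 seed = smp_seed)
        lseg <- seg_loss_node(fw$y_hat, t(sp$mask), weights$epsilon)
        ldiv <- diversity_loss_node(fw$aux$attn)
        lent <- routing_entropy_node(fw$aux$s1_alpha)
        if (phase == 1L) {
          ltotal <- lseg
          lbal_v <- 0; lsp_v <- 0
        } else {
          lbal <- ad_mul(ad_add(balance_loss_node(fw$aux$s1_alpha),
                                balance_loss_node(fw$aux$s2_alpha)), 0.5)
          lsp <- sparsity_loss_node(fw$aux$attn)
          ltotal <- ad_add(ad_add(ad_mul(lseg, weights$lambda_seg),
                                  ad_mul(lbal, lam1)),
                           ad_mul(lsp, weights$lambda2))
          if (lambda_diversity != 0)
            ltotal <- ad_add(ltotal, ad_mul(ldiv, lambda_diversity))
          if (lambda_entropy != 0)
            ltotal <- ad_add(ltotal, ad_mul(lent, lambda_entropy))
          lbal_v <- lbal$value; lsp_v <- lsp$value
        }
        if (!is.finite(ltotal$value))
          stop("non-finite loss at epoch ", epoch, ", sample ", i,
               " (seg=", lseg$value, ")")
        ad_backward(ltotal)
        g <- param_grads(fw$ctx)
        grads <- if (is.null(grads)) g else {
          for (nm in names(g)) grads[[nm]] <- (grads[[nm]] %||% 0) + g[[nm]]
          grads
        }
        ep_loss <- ep_loss + c(lseg$value, lbal_v, lsp_v, ltotal$value)
        ep_aux <- ep_aux + c(ldiv$value, lent$value)
        decisions[[length(decisions) + 1L]] <- fw$aux$s1_decision
      }
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / length(bidx)
      frozen <- if (phase == 1L) enc_names else character(0)
      st <- adamw_step(model$params, grads, opt, lr_for,
                       weight_decay = schedule$weight_decay,
                       clip_norm = schedule$grad_clip, frozen = frozen)
      model$params <- st$params
      opt <- st$state
      n_batches <- n_batches + 1L
    }
    ustats <- utilization(decisions)
    ent_track <- c(ent_track, ustats$entropy_bits)
    history[[epoch]] <- data.frame(
      epoch = epoch, phase = phase, tau = tau, lr_encoder = lr_enc,
      lr_decoder = lr_dec, lambda1_effective = lam1,
      l_seg = ep_loss[["seg"]] / n, l_balance = ep_loss[["balance"]] / n,
      l_sparsity = ep_loss[["sparsity"]] / n,
      l_total = ep_loss[["total"]] / n,
      l_diversity = ep_aux[["diversity"]] / n,
      l_routing_entropy = ep_aux[["entropy"]] / n,
      utilization_entropy = ustats$entropy_bits, gini = ustats$gini)
    if (verbose)
      message(sprintf("epoch %d phase %d seg %.4f total %.4f ent %.3f",
                      epoch, phase, ep_loss[["seg"]] / n,
                      ep_loss[["total"]] / n, ustats$entropy_bits))
    if (phase == 3L && length(ent_track) > schedule$early_stop_window) {
      w <- schedule$early_stop_window
      recent <- utils::tail(ent_track, w + 1L)
      if (max(abs(diff(recent))) < schedule$early_stop_delta) {
        stopped_early <- TRUE
        break
      }
    }
  }
  hist <- do.call(rbind, history)
  best_val_iou <- NA_real_
  if (!is.null(val_scenes)) {
    ev <- evaluate_model(model, val_scenes)
    best_val_iou <- ev$mean_iou
  }
  structure(list(model = model, optimizer = opt, epoch = max(hist$epoch),
                 history = hist, schedule = schedule, weights = weights,
                 best_val_iou = best_val_iou,
                 stopped_early = stopped_early),
            class = "checkpoint")
}

#' Evaluate a model over scenes
#'
#' Thresholds the predicted probability mask at 0.5 and aggregates IoU,
#' Dice, precision, recall and (where both boundaries exist) the symmetric
#' Hausdorff distance.
#'
#' @param model a trained [build_model()] object (or a `checkpoint`).
#' @param scenes list of scenes or image/mask pairs.
#' @param threshold binarization threshold.
#' @return list(per_image = data frame, mean_iou, mean_dice,
#'   mean_precision, mean_recall, mean_hausdorff).
#' @export
evaluate_model <- function(model, scenes, threshold = 0.5) {
  if (inherits(model, "checkpoint")) model <- model$model
  rows <- lapply(seq_along(scenes), function(i) {
    sp <- scene_pair(scenes[[i]])
    fw <- forward(sp$image, model, mode = "eval")
    pred <- (fw$y_hat >= threshold) * 1L
    m <- segmentation_metrics(pred, sp$mask)
    hd <- if (sum(pred) > 0 && sum(sp$mask) > 0)
      mask_hausdorff(pred, sp$mask) else NA_real_
    data.frame(index = i, iou = m$iou, dice = m$dice,
               precision = m$precision, recall = m$recall, hausdorff = hd)
  })
  per <- do.call(rbind, rows)
  list(per_image = per, mean_iou = mean(per$iou), mean_dice = mean(per$dice),
       mean_precision = mean(per$precision),
       mean_recall = mean(per$recall),
       mean_hausdorff = mean(per$hausdorff, na.rm = TRUE))
}

#' Save / load a checkpoint
#'
#' Single-file archive embedding the model configuration, weights,
#' optimizer state and training history; reloading reproduces identical
#' eval-mode outputs.
#'
#' @param checkpoint a `checkpoint` (or bare `moe_model`).
#' @param path file path.
#' @export
checkpoint_save <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(path) readRDS(path)

#' Default configuration values
#'
#' Reads the packaged default configuration (training hyperparameters,
#' sparse-attention and MoE settings, loss weights, augmentation).
#'
#' @return Named list.
#' @export
default_config <- function() {
  yaml::read_yaml(system.file("config", "default.yaml",
                              package = "sparsemoeseg"))
}
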