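#' Construct a single-center training batch
#'
#' In traveling-model mode every batch is drawn from one center's shard, so
#' all samples share a center id; this is the structural property that makes
#' the traveling model comparatively resistant to scanner shortcuts.
#'
#' @param volumes list of 3D arrays (N >= 1).
#' @param y_disease binary vector of length N.
#' @param scanner_ids integer vector of scanner type ids in `1..M`.
#' @param M size of the global scanner label space.
#' @param center_id id of the center the batch was drawn from (`NA` allowed
#'   in centralized mode, where batches may mix centers).
#' @return An object of class `tm_batch` with a one-hot `y_scanner` matrix.
#' @export
tm_batch <- function(volumes, y_disease, scanner_ids, M, center_id = NA) {
  if (!is.list(volumes)) volumes <- list(volumes)
  N <- length(volumes)
  if (N < 1) stop("empty batch")
  if (length(y_disease) != N || length(scanner_ids) != N)
    stop("labels must match the number of volumes")
  if (any(!y_disease %in% c(0, 1))) stop("disease labels must be binary")
  structure(list(volumes = volumes,
                 y_disease = as.numeric(y_disease),
                 y_scanner = one_hot(scanner_ids, M),
                 scanner_ids = as.integer(scanner_ids),
                 center_id = center_id,
                 N = N),
            class = "tm_batch")
}

#' Independent optimizer states for the three harmonization sub-updates
#'
#' Step 1 (encoder + disease head), step 2 (scanner head) and step 3
#' (encoder) each keep their own Adam state, so the freeze contracts act on
#' disjoint parameter groups.
#'
#' @return A list with components `task`, `scanner`, `conf`.
#' @export
harmon_optimizers <- function() {
  list(task = adam_init(), scanner = adam_init(), conf = adam_init())
}

# ---- the three sub-updates --------------------------------------------------

# Step 1: optimize encoder + disease head for the disease task.  During
# task-only pre-training the forward pass uses batch statistics and commits
# running stats ("train"); inside the harmonization procedure it uses the
# frozen running statistics ("finetune") so the adversarial game acts on the
# same normalization the deployed model uses.
step_task <- function(batch, bundle, opt, lr, bn_mode = "train") {
  x <- stack_volumes(batch$volumes)
  fw <- nn_encoder_forward(bundle$encoder, bundle$config, x, mode = bn_mode,
                           want_cache = TRUE)
  feats <- fw$features
  p <- as.vector(nn_sigmoid(feats %*% bundle$disease_head$w + bundle$disease_head$b))
  l <- loss_pd(batch$y_disease, .clip01(p))
  N <- batch$N
  dlogit <- matrix((p - batch$y_disease) / N, N, 1)
  gdh <- list(w = crossprod(feats, dlogit), b = sum(dlogit))
  gfeat <- dlogit %*% t(bundle$disease_head$w)
  genc <- nn_encoder_backward(bundle$encoder, fw$cache, gfeat)
  upd <- adam_step(list(encoder = enc_trainable(bundle$encoder),
                        disease = bundle$disease_head),
                   list(encoder = genc, disease = gdh),
                   opt$task, lr)
  opt$task <- upd$state
  bundle$encoder <- enc_set_trainable(bundle$encoder, upd$params$encoder)
  bundle$disease_head <- upd$params$disease
  if (lr != 0 && bn_mode == "train")
    bundle$encoder <- enc_commit_stats(bundle$encoder, fw$stats)
  list(bundle = bundle, opt = opt, loss = l, gfeat_norm = sqrt(sum(gfeat^2)))
}

# Step 2: optimize the scanner head on features from the frozen encoder
# (running-stat normalization, dropout on, no stat commits): the encoder --
# parameters and running stats -- is bitwise unchanged.
step_scanner <- function(batch, bundle, opt, lr) {
  x <- stack_volumes(batch$volumes)
  fw <- nn_encoder_forward(bundle$encoder, bundle$config, x, mode = "finetune")
  feats <- fw$features
  P <- nn_softmax(sweep(feats %*% bundle$scanner_head$w, 2, bundle$scanner_head$b, "+"))
  l <- loss_scanner(batch$y_scanner, P)
  N <- batch$N
  dz <- (P - batch$y_scanner) / N
  gsh <- list(w = crossprod(feats, dz), b = colSums(dz))
  upd <- adam_step(list(scanner = bundle$scanner_head),
                   list(scanner = gsh), opt$scanner, lr)
  opt$scanner <- upd$state
  bundle$scanner_head <- upd$params$scanner
  list(bundle = bundle, opt = opt, loss = l)
}

# Step 3: optimize the encoder against the confusion loss, driving the
# (fixed) scanner head toward chance-level output.  Uses the frozen running
# statistics, like step 1 inside the harmonization procedure.
step_confusion <- function(batch, bundle, opt, lr, optimizer = "sgd",
                           cap_norm = Inf) {
  x <- stack_volumes(batch$volumes)
  fw <- nn_encoder_forward(bundle$encoder, bundle$config, x, mode = "finetune",
                           want_cache = TRUE)
  feats <- fw$features
  P <- nn_softmax(sweep(feats %*% bundle$scanner_head$w, 2, bundle$scanner_head$b, "+"))
  l <- loss_confusion(P)
  N <- batch$N
  M <- bundle$M
  dz <- (P - 1 / M) / N
  gfeat <- dz %*% t(bundle$scanner_head$w)
  # Trust coupling: the adversarial feature gradient is capped at the norm
  # of the task step's feature gradient on the same batch, so the confusion
  # pressure scales with (and cannot drown) the disease signal; this keeps
  # the degenerate collapsed representation out of reach.
  gn <- sqrt(sum(gfeat^2))
  if (is.finite(cap_norm) && gn > cap_norm && gn > 0)
    gfeat <- gfeat * (cap_norm / gn)
  genc <- nn_encoder_backward(bundle$encoder, fw$cache, gfeat)
  if (optimizer == "sgd") {
    new_tr <- sgd_step(enc_trainable(bundle$encoder), genc, lr)
  } else {
    upd <- adam_step(list(encoder = enc_trainable(bundle$encoder)),
                     list(encoder = genc), opt$conf, lr)
    opt$conf <- upd$state
    new_tr <- upd$params$encoder
  }
  bundle$encoder <- enc_set_trainable(bundle$encoder, new_tr)
  list(bundle = bundle, opt = opt, loss = l)
}

#' One per-batch harmonization step
#'
#' The three-step adversarial procedure applied to a single batch:
#' \enumerate{
#'   \item optimize the encoder and disease head for disease classification
#'     ([loss_pd()]);
#'   \item optimize the scanner head to identify scanners from the frozen
#'     encoder's features ([loss_scanner()]); the encoder is bitwise
#'     unchanged by this sub-update;
#'   \item optimize the encoder with the adversarial confusion loss
#'     ([loss_confusion()]); the scanner head is bitwise unchanged by this
#'     sub-update.
#' }
#' The three losses and their exact sum are returned as a [loss_record()].
#' With `combined = TRUE` the encoder instead receives a single update with
#' the summed disease + confusion gradient from one forward pass (the total
#' loss applied directly); the default sequential alternation is what keeps
#' the scanner head an up-to-date adversary.
#'
#' @param batch a [tm_batch()].
#' @param bundle a [model_bundle()] (pre-trained; see [pretrain()]).
#' @param opt optimizer states from [harmon_optimizers()].
#' @param lr learning rate of sub-update 1 (zero learning rates throughout
#'   leave the bundle bit-identical).
#' @param lr_scanner,lr_conf learning rates of sub-updates 2 and 3
#'   (default `lr`); the adversarial balance can be tilted by scaling the
#'   confusion update relative to the task update.
#' @param combined apply a single combined encoder update instead of the
#'   sequential sub-updates.
#' @return `list(bundle, opt, record)`.
#' @export
harmonization_step <- function(batch, bundle, opt, lr, lr_scanner = lr,
                               lr_conf = lr, combined = FALSE) {
  stopifnot(inherits(batch, "tm_batch"), inherits(bundle, "model_bundle"))
  if (batch$N == 0) stop("empty batch")
  if (ncol(batch$y_scanner) != bundle$M)
    stop("batch scanner label space does not match the bundle")
  if (combined)
    return(harmonization_step_combined(batch, bundle, opt, lr,
                                       conf_weight = if (lr > 0) lr_conf / lr else 1))
  s1 <- step_task(batch, bundle, opt, lr, bn_mode = "finetune")
  s2 <- step_scanner(batch, s1$bundle, s1$opt, lr_scanner)
  s3 <- step_confusion(batch, s2$bundle, s2$opt, lr_conf)
  list(bundle = s3$bundle, opt = s3$opt,
       record = loss_record(s1$loss, s2$loss, s3$loss))
}

# Combined variant: one forward pass; encoder gets the summed disease +
# confusion gradient, disease head the disease gradient, scanner head the
# scanner gradient.
harmonization_step_combined <- function(batch, bundle, opt, lr, conf_weight = 1) {
  x <- stack_volumes(batch$volumes)
  fw <- nn_encoder_forward(bundle$encoder, bundle$config, x, mode = "finetune",
                           want_cache = TRUE)
  feats <- fw$features
  N <- batch$N
  M <- bundle$M
  p <- as.vector(nn_sigmoid(feats %*% bundle$disease_head$w + bundle$disease_head$b))
  P <- nn_softmax(sweep(feats %*% bundle$scanner_head$w, 2, bundle$scanner_head$b, "+"))
  l1 <- loss_pd(batch$y_disease, .clip01(p))
  l2 <- loss_scanner(batch$y_scanner, P)
  l3 <- loss_confusion(P)
  dlogit <- matrix((p - batch$y_disease) / N, N, 1)
  dz_sc <- (P - batch$y_scanner) / N
  dz_cf <- (P - 1 / M) / N
  gdh <- list(w = crossprod(feats, dlogit), b = sum(dlogit))
  gsh <- list(w = crossprod(feats, dz_sc), b = colSums(dz_sc))
  gf_task <- dlogit %*% t(bundle$disease_head$w)
  gf_conf <- dz_cf %*% t(bundle$scanner_head$w)
  # Trust coupling: the adversarial component of the feature gradient is
  # capped at conf_weight times the task component's norm (plus a small
  # absolute floor so bounded confusion pressure persists once the disease
  # loss has converged and its gradient vanishes).  The confusion pressure
  # therefore scales with, and can never drown, the disease signal; this
  # keeps the absorbing all-dead-feature solution of the confusion
  # objective out of reach.
  nt <- sqrt(sum(gf_task^2))
  nc <- sqrt(sum(gf_conf^2))
  cap <- conf_weight * (nt + 0.01 * sqrt(batch$N))
  if (nc > cap && nc > 0) gf_conf <- gf_conf * (cap / nc)
  gfeat <- gf_task + gf_conf
  genc <- nn_encoder_backward(bundle$encoder, fw$cache, gfeat)
  upd <- adam_step(list(encoder = enc_trainable(bundle$encoder),
                        disease = bundle$disease_head,
                        scanner = bundle$scanner_head),
                   list(encoder = genc, disease = gdh, scanner = gsh),
                   opt$task, lr)
  opt$task <- upd$state
  bundle$encoder <- enc_set_trainable(bundle$encoder, upd$params$encoder)
  bundle$disease_head <- upd$params$disease
  bundle$scanner_head <- upd$params$scanner
  list(bundle = bundle, opt = opt, record = loss_record(l1, l2, l3))
}

#' Two-phase pre-training
#'
#' Phase A trains the encoder and disease head on the disease task with the
#' traveling-model schedule; the scanner head is untouched.  Phase B freezes
#' the encoder (bitwise) and trains the scanner head, again on the
#' traveling-model schedule.  "Until convergence" is realized as fixed cycle
#' budgets (`pretrain_cycles_task`, `pretrain_cycles_scanner` in
#' [tm_config()]), which keeps desk-scale runs reproducible.
#'
#' @param shards list of center shards from [generate_cohort()].
#' @param bundle a freshly initialized [model_bundle()].
#' @param tm_config a [tm_config()].
#' @return `list(bundle, history_task, history_scanner)`.
#' @export
pretrain <- function(shards, bundle, tm_config) {
  if (length(shards) == 0) stop("empty cohort")
  cfg_a <- tm_config
  cfg_a$n_cycles <- tm_config$pretrain_cycles_task
  a <- run_tm(shards, bundle, cfg_a, mode = "task_only")
  cfg_b <- tm_config
  cfg_b$n_cycles <- tm_config$pretrain_cycles_scanner
  cfg_b$seed <- derive_seed(tm_config$seed, "pretrain_b")
  b <- run_tm(shards, a$bundle, cfg_b, mode = "scanner_head")
  list(bundle = b$bundle, history_task = a$history, history_scanner = b$history)
}
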