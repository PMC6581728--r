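# Splicing-code and AS-conservation classifiers: balancing, stratified
# splitting, a small feed-forward network (tanh activation, three hidden
# layers by default, softmax output, Adam optimiser, seeded and
# deterministic), validation-AUC hyperparameter selection, rank-based AUC
# and permutation importance.

#' Balance a binary dataset by subsampling the majority class
#'
#' All `alternative` rows are kept; `constitutive` rows are subsampled
#' (seeded) to the same number, mirroring the negative-example selection
#' used for the splicing-code models.
#'
#' @param data data frame with a two-level factor column `label`; the
#'   second level is the positive (minority) class.
#' @param seed subsampling seed.
#' @return balanced data frame.
#' @export
balance_binary <- function(data, seed = 1L) {
  lv <- levels(data$label)
  stopifnot(length(lv) == 2L)
  n_pos <- sum(data$label == lv[2]); n_neg <- sum(data$label == lv[1])
  if (n_pos == 0L || n_neg == 0L) stopf("both classes must be non-empty")
  if (n_pos > n_neg)
    stopf("positive class (%d) larger than negative (%d); cannot balance",
          n_pos, n_neg)
  neg_idx <- which(data$label == lv[1])
  keep_neg <- with_seed(derive_seed(seed, 23L),
                        sample(neg_idx, n_pos))
  out <- rbind(data[data$label == lv[2], , drop = FALSE],
               data[sort(keep_neg), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Stratified train/validation/test split
#'
#' Disjoint, exhaustive and stratified by class; sizes within one row of
#' the exact fractions per class.
#'
#' @param data data frame with a `label` column.
#' @param fractions numeric of length 3 summing to 1 (default 0.6/0.2/0.2).
#' @param seed split seed.
#' @return list with `train`, `validation`, `test`.
#' @export
split_dataset <- function(data, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stopf("fractions must sum to 1")
  if (nrow(data) < 10L) stopf("need at least 10 rows to split")
  idx <- with_seed(derive_seed(seed, 31L), {
    parts <- list(integer(0), integer(0), integer(0))
    for (lv in levels(factor(data$label))) {
      rows <- sample(which(data$label == lv))
      n <- length(rows)
      n1 <- round(fractions[1] * n)
      n2 <- round(fractions[2] * n)
      parts[[1]] <- c(parts[[1]], rows[seq_len(n1)])
      parts[[2]] <- c(parts[[2]], rows[n1 + seq_len(min(n2, n - n1))])
      if (n1 + n2 < n)
        parts[[3]] <- c(parts[[3]], rows[(n1 + n2 + 1L):n])
    }
    parts
  })
  list(train = data[sort(idx[[1]]), , drop = FALSE],
       validation = data[sort(idx[[2]]), , drop = FALSE],
       test = data[sort(idx[[3]]), , drop = FALSE])
}

# ---- feed-forward network ------------------------------------------------

.model_matrix <- function(data) {
  num <- vapply(data, is.numeric, logical(1))
  num["label"] <- FALSE
  drop <- intersect(names(data), c("junction_id", "gene_id", "pair_id"))
  x <- as.matrix(data[, setdiff(names(data)[num], drop), drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    bad <- colnames(x)[apply(!is.finite(x), 2L, any)]
    stopf("non-finite feature values in column(s): %s",
          paste(bad, collapse = ", "))
  }
  x
}

.mlp_init <- function(sizes, rng_sd = 0.3) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                           rng_sd / sqrt(sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(par, x) {
  a <- list(x)
  nl <- length(par$W)
  for (l in seq_len(nl)) {
    z <- a[[l]] %*% par$W[[l]] +
      matrix(par$b[[l]], nrow(x), length(par$b[[l]]), byrow = TRUE)
    a[[l + 1L]] <- if (l < nl) tanh(z) else z
  }
  zout <- a[[nl + 1L]]
  zout <- zout - apply(zout, 1L, max)
  e <- exp(zout)
  p <- e / rowSums(e)
  list(activations = a, probs = p)
}

.mlp_grad <- function(par, x, y_onehot, l2) {
  fw <- .mlp_forward(par, x)
  n <- nrow(x); nl <- length(par$W)
  delta <- (fw$probs - y_onehot) / n
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(fw$activations[[l]], delta) + l2 * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$W[[l]])) * (1 - fw$activations[[l]]^2)
    }
  }
  list(W = gW, b = gb, probs = fw$probs)
}

.logloss <- function(probs, y_idx) {
  p <- probs[cbind(seq_along(y_idx), y_idx)]
  -mean(log(pmax(p, 1e-12)))
}

# Train a softmax feed-forward network with Adam (full batch).
# Early stopping: validation logloss evaluated every `eval_every` epochs;
# stop when the best loss has improved by < 1% over the last 10
# evaluations.  Deterministic given seed.
.mlp_fit <- function(x, y, hidden = c(8L, 8L, 8L), l2 = 1e-3, lr = 0.05,
                     epochs = 400L, seed = 1L, x_val = NULL, y_val = NULL,
                     eval_every = 10L) {
  classes <- levels(y)
  y_idx <- as.integer(y)
  k <- length(classes)
  ctr <- colMeans(x); scl <- apply(x, 2L, sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  onehot <- matrix(0, nrow(x), k)
  onehot[cbind(seq_len(nrow(x)), y_idx)] <- 1
  sizes <- c(ncol(x), hidden, k)
  par <- with_seed(derive_seed(seed, 41L), .mlp_init(sizes))
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  val_hist <- numeric(0)
  stopped_at <- epochs
  if (!is.null(x_val)) xvs <- scale(x_val, ctr, scl)
  for (t in seq_len(epochs)) {
    g <- .mlp_grad(par, xs, onehot, l2)
    for (l in seq_along(par$W)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
      par$W[[l]] <- par$W[[l]] -
        lr * (mW[[l]] / (1 - b1^t)) / (sqrt(vW[[l]] / (1 - b2^t)) + eps)
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
      par$b[[l]] <- par$b[[l]] -
        lr * (mb[[l]] / (1 - b1^t)) / (sqrt(vb[[l]] / (1 - b2^t)) + eps)
    }
    if (!is.null(x_val) && t %% eval_every == 0L) {
      pv <- .mlp_forward(par, xvs)$probs
      val_hist <- c(val_hist, .logloss(pv, as.integer(y_val)))
      if (length(val_hist) > 10L) {
        recent_best <- min(tail(val_hist, 10L))
        prior_best <- min(head(val_hist, length(val_hist) - 10L))
        if (recent_best > prior_best * 0.99) { stopped_at <- t; break }
      }
    }
  }
  structure(list(par = par, center = ctr, scale = scl, classes = classes,
                 hidden = hidden, l2 = l2, lr = lr,
                 epochs_run = stopped_at, feature_names = colnames(x)),
            class = "splice_mlp")
}

#' Predict class probabilities from a trained classifier
#'
#' @param object a `splice_mlp` model.
#' @param newdata data frame or matrix of features.
#' @param ... unused.
#' @return matrix of class probabilities (columns named by class).
#' @export
predict.splice_mlp <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) .model_matrix(newdata) else newdata
  x <- x[, object$feature_names, drop = FALSE]
  xs <- scale(x, object$center, object$scale)
  p <- .mlp_forward(object$par, xs)$probs
  colnames(p) <- object$classes
  p
}

#' Train the splicing-code classifier
#'
#' Hyperparameters (from a small declared grid) are selected by validation
#' AUC; the selected configuration is then refit on the union of training
#' and validation data.  The reference configuration is a feed-forward
#' network with three hidden tanh layers.  Deterministic given `seed`.
#'
#' @param train,validation data frames with `label` and numeric features.
#' @param config list; `grid` is a list of hyperparameter lists with
#'   elements `hidden`, `l2`, `lr`; `epochs` caps training length.
#' @param seed integer seed.
#' @return object of class `splice_mlp` with `validation_auc` attached.
#' @export
train_classifier <- function(train, validation, config = list(),
                             seed = 1L) {
  grid <- config$grid %||% list(
    list(hidden = c(8L, 8L, 8L), l2 = 1e-3, lr = 0.05),
    list(hidden = c(16L, 8L, 4L), l2 = 1e-2, lr = 0.05))
  epochs <- config$epochs %||% 400L
  x_tr <- .model_matrix(train); y_tr <- droplevels(factor(train$label))
  x_va <- .model_matrix(validation)
  y_va <- factor(validation$label, levels = levels(y_tr))
  best <- NULL; best_auc <- -Inf; best_cfg <- NULL
  for (gi in seq_along(grid)) {
    cfgi <- grid[[gi]]
    fit <- .mlp_fit(x_tr, y_tr, hidden = cfgi$hidden, l2 = cfgi$l2,
                    lr = cfgi$lr, epochs = epochs,
                    seed = derive_seed(seed, 100L + gi),
                    x_val = x_va, y_val = y_va)
    p <- predict(fit, x_va)
    auc <- .multi_auc(p, y_va)
    if (auc > best_auc) { best_auc <- auc; best <- fit; best_cfg <- cfgi }
  }
  # refit on the full available data with the selected hyperparameters
  x_all <- rbind(x_tr, x_va)
  y_all <- factor(c(as.character(y_tr), as.character(y_va)),
                  levels = levels(y_tr))
  final <- .mlp_fit(x_all, y_all, hidden = best_cfg$hidden,
                    l2 = best_cfg$l2, lr = best_cfg$lr,
                    epochs = best$epochs_run,
                    seed = derive_seed(seed, 199L))
  attr(final, "validation_auc") <- best_auc
  attr(final, "selected") <- best_cfg
  final
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen positive is scored above a
#' randomly chosen negative; ties contribute 0.5 (Mann-Whitney estimate).
#'
#' @param scores numeric scores.
#' @param labels logical, or factor whose second level is positive.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stopf("NA in scores or labels")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# macro-averaged one-vs-rest AUC for a probability matrix
.multi_auc <- function(probs, labels) {
  labels <- factor(labels)
  if (nlevels(labels) == 2L)
    return(compute_auc(probs[, levels(labels)[2]], labels))
  mean(vapply(levels(labels), function(lv)
    compute_auc(probs[, lv], labels == lv), numeric(1)))
}

#' Model evaluation metrics
#'
#' AUC (macro-averaged one-vs-rest for more than two classes), accuracy,
#' specificity, precision, and a Wilcoxon-based p-value against chance
#' ranking.
#'
#' @param model trained classifier.
#' @param data data frame with `label`.
#' @return list of metrics.
#' @export
evaluate_classifier <- function(model, data) {
  p <- predict(model, data)
  y <- factor(data$label, levels = model$classes)
  pred <- factor(model$classes[max.col(p)], levels = model$classes)
  auc <- .multi_auc(p, y)
  acc <- mean(pred == y)
  if (nlevels(y) == 2L) {
    pos <- levels(y)[2]; neg <- levels(y)[1]
    tp <- sum(pred == pos & y == pos); fp <- sum(pred == pos & y == neg)
    tn <- sum(pred == neg & y == neg)
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    s <- p[, pos]
    pval <- stats::wilcox.test(s[y == pos], s[y == neg],
                               alternative = "greater", exact = FALSE)$p.value
  } else {
    spec <- prec <- pval <- NA_real_
  }
  list(auc = auc, accuracy = acc, specificity = spec, precision = prec,
       p_value = pval)
}

#' Permutation variable importance
#'
#' Mean AUC drop over `R` seeded permutations of each feature on held-out
#' data, ranked descending.
#'
#' @param model trained classifier.
#' @param data held-out data frame with `label`.
#' @param R permutations per feature (default 20).
#' @param seed integer seed.
#' @return data frame `feature`, `importance`, sorted descending.
#' @export
variable_importance <- function(model, data, R = 20L, seed = 1L) {
  x <- .model_matrix(data)
  y <- factor(data$label, levels = model$classes)
  base_auc <- .multi_auc(predict(model, x), y)
  imp <- with_seed(derive_seed(seed, 57L), {
    vapply(model$feature_names, function(f) {
      drops <- vapply(seq_len(R), function(r) {
        xp <- x
        xp[, f] <- sample(xp[, f])
        base_auc - .multi_auc(predict(model, xp), y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Fit the AS-conservation model (best of `repeats` balanced fits)
#'
#' Per repeat: a reseeded 1:1:1 subsample over conserved/lost/gained, a
#' 60/20/20 stratified split, training with validation-AUC selection, and
#' evaluation on the complete dataset; the repeat with the highest
#' complete-dataset AUC wins.
#'
#' @param data data frame with a three-level `label` and numeric features.
#' @param repeats number of repeats (default 10).
#' @param seed integer seed.
#' @param config passed to [train_classifier()].
#' @return list with `model`, `metrics` (complete-dataset), `per_repeat`
#'   data frame, `n_per_class`.
#' @export
fit_conservation_model <- function(data, repeats = 10L, seed = 1L,
                                   config = list()) {
  data$label <- droplevels(factor(data$label))
  lv <- levels(data$label)
  if (length(lv) != 3L) stopf("expected three classes, got: %s",
                              paste(lv, collapse = ", "))
  counts <- table(data$label)
  n_min <- min(counts)
  if (n_min < 10L)
    stopf("class '%s' has only %d rows (need >= 10)",
          names(counts)[which.min(counts)], n_min)
  best <- NULL; best_auc <- -Inf
  per_repeat <- numeric(repeats)
  for (r in seq_len(repeats)) {
    sub <- with_seed(derive_seed(seed, 300L + r), {
      idx <- unlist(lapply(lv, function(l)
        sample(which(data$label == l), n_min)))
      sort(idx)
    })
    d <- data[sub, , drop = FALSE]
    sp <- split_dataset(d, seed = derive_seed(seed, 400L + r))
    fit <- train_classifier(sp$train, sp$validation, config = config,
                            seed = derive_seed(seed, 500L + r))
    auc <- .multi_auc(predict(fit, data), data$label)
    per_repeat[r] <- auc
    if (auc > best_auc) { best_auc <- auc; best <- fit }
  }
  list(model = best,
       metrics = evaluate_classifier(best, data),
       complete_auc = best_auc,
       per_repeat = data.frame(repeat_id = seq_len(repeats),
                               complete_auc = per_repeat),
       n_per_class = n_min)
}

#' Flank similarity of two sequences
#'
#' Global pairwise alignment;
#' `(alignment length - gaps - mismatches) / alignment length`.
#'
#' @param a,b nucleotide sequences.
#' @return similarity in `[0, 1]`.
#' @export
flank_similarity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(pattern = a, subject = b,
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  len <- length(pa)
  gaps <- sum(pa == "-") + sum(sa == "-")
  mism <- sum(pa != "-" & sa != "-" & pa != sa)
  similarity_from_alignment(len, gaps, mism)
}

#' Similarity from alignment statistics
#'
#' @param aln_length alignment length (total sequence length including
#'   gap columns).
#' @param gaps number of gap positions.
#' @param mismatches number of mismatched positions.
#' @return `(aln_length - gaps - mismatches) / aln_length`.
#' @export
similarity_from_alignment <- function(aln_length, gaps, mismatches) {
  (aln_length - gaps - mismatches) / aln_length
}

#' Build the AS-conservation dataset (cross-species feature differences)
#'
#' Joins per-junction feature rows of two species on the matched-EEJ
#' conservation labels and emits the feature differences (first minus
#' second species) plus flank similarity and GC-content change when EEJ
#' sequences are supplied.  Only `conserved`, `lost` and `gained` pairs
#' are retained.
#'
#' @param feat_a,feat_b outputs of [build_feature_matrix()] (use
#'   `all_genes = TRUE`).
#' @param labels output of [call_conservation()].
#' @param eejs_a,eejs_b optional outputs of [build_eej_table()] for flank
#'   similarity and GC change.
#' @return data frame with `label` and difference features.
#' @export
build_conservation_dataset <- function(feat_a, feat_b, labels,
                                       eejs_a = NULL, eejs_b = NULL) {
  keep <- labels$state %in% c("conserved", "lost", "gained")
  lab <- labels[keep, , drop = FALSE]
  ia <- match(lab$junction_a, feat_a$junction_id)
  ib <- match(lab$junction_b, feat_b$junction_id)
  ok <- !is.na(ia) & !is.na(ib)
  lab <- lab[ok, ]; ia <- ia[ok]; ib <- ib[ok]
  if (!nrow(lab)) return(NULL)
  num_cols <- c("junction_size", "has_alt_ss", "dist_alt_ss",
                "frame_alt_ss", "has_inter_gtag", "dist_inter_gtag",
                "frame_inter_gtag", "ppt_present", "ua_present",
                "branch_present", "mean_reads")
  diff <- as.data.frame(feat_a[ia, num_cols] - feat_b[ib, num_cols])
  names(diff) <- paste0("d_", num_cols)
  out <- cbind(data.frame(pair_id = paste(lab$junction_a, lab$junction_b,
                                          sep = "|"),
                          label = factor(lab$state,
                                         levels = c("conserved", "gained",
                                                    "lost")),
                          stringsAsFactors = FALSE),
               diff)
  if (!is.null(eejs_a) && !is.null(eejs_b)) {
    sa <- eejs_a$seq[match(lab$junction_a, eejs_a$junction_id)]
    sb <- eejs_b$seq[match(lab$junction_b, eejs_b$junction_id)]
    gc <- function(s) {
      b <- strsplit(toupper(s), "")[[1]]
      mean(b %in% c("G", "C"))
    }
    out$flank_similarity <- mapply(flank_similarity, sa, sb)
    out$d_gc_content <- vapply(sa, gc, 0) - vapply(sb, gc, 0)
  }
  rownames(out) <- NULL
  out
}
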