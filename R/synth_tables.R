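# Synthetic tabular data with known ground truth: two-class lesion feature
# tables with sparse discriminative structure, exponential survival records,
# and lognormal metabolite matrices with class-dependent elevation of a
# designated acyl-carnitine-like block.

#' Two-class lesion feature table with sparse signal
#'
#' Features are standard normal; class-1 lesions receive a mean shift of
#' \code{effect_size} on the \code{support} features only, so the Bayes
#' separation is known (\eqn{AUC = \Phi(d/\sqrt{2})} for a single feature
#' of effect d).
#'
#' @param n_lesions rows; n_features columns.
#' @param n_features number of feature columns.
#' @param support number of discriminative features (or an index vector).
#' @param effect_size class-conditional mean shift on support features.
#' @param class_balance probability of class 1.
#' @param seed integer seed.
#' @return list: features (data.frame F1..Fn), labels (0/1), support
#'   (indices), effect_size.
#' @export
simulate_feature_table <- function(n_lesions = 200, n_features = 20,
                                   support = 3, effect_size = 1,
                                   class_balance = 0.5, seed = 1) {
  if (length(support) == 1L) {
    if (support > n_features) stop("support larger than n_features")
    support <- seq_len(support)
  }
  if (max(support) > n_features) stop("support index out of range")
  with_seed(seed, {
    labels <- as.integer(runif(n_lesions) < class_balance)
    x <- matrix(rnorm(n_lesions * n_features), n_lesions, n_features)
    x[, support] <- x[, support] + outer(labels, rep(effect_size,
                                                     length(support)))
    colnames(x) <- paste0("F", seq_len(n_features))
    list(features = as.data.frame(x), labels = labels, support = support,
         effect_size = effect_size)
  })
}

#' Exponential survival records with independent censoring
#'
#' Event times are exponential (true median = ln 2 / rate). Either a single
#' rate, per-group rates, or a feature-linked proportional hazard
#' \eqn{rate_i = rate \cdot e^{\beta x_i}} may be specified. Each record is
#' independently censored with probability \code{censoring_rate}, at a
#' uniform time before its event.
#'
#' @param n records (per group when \code{group_rates} is named).
#' @param rate events per month (ignored when group_rates given).
#' @param group_rates named vector of rates, one group per element.
#' @param linked_feature,beta optional covariate and log-hazard slope.
#' @param censoring_rate probability a record is censored.
#' @param seed integer seed.
#' @return data.frame: id, time_months, event (1 = event, 0 = censored),
#'   group, plus the linked feature when supplied.
#' @export
simulate_survival <- function(n = 100, rate = log(2) / 10,
                              group_rates = NULL, linked_feature = NULL,
                              beta = 0, censoring_rate = 0.2, seed = 1) {
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("censoring_rate must be in [0, 1]")
  with_seed(seed, {
    if (!is.null(group_rates)) {
      if (any(group_rates <= 0)) stop("rates must be positive")
      grp <- rep(names(group_rates), each = n)
      rt <- rep(unname(group_rates), each = n)
    } else {
      if (rate <= 0) stop("rate must be positive")
      grp <- rep("all", n)
      rt <- rep(rate, n)
      if (!is.null(linked_feature)) {
        stopifnot(length(linked_feature) == n)
        rt <- rate * exp(beta * linked_feature)
      }
    }
    tt <- rexp(length(rt), rt)
    cens <- runif(length(rt)) < censoring_rate
    obs <- ifelse(cens, runif(length(rt)) * tt, tt)
    out <- data.frame(id = seq_along(rt), time_months = obs,
                      event = as.integer(!cens), group = grp)
    if (!is.null(linked_feature) && is.null(group_rates))
      out$feature <- linked_feature
    out
  })
}

#' Lognormal metabolite matrix with class-dependent block elevation
#'
#' Log-normal abundances for three groups (default sizes matching a
#' low-grade glioma / high-grade glioma / metastasis design). A designated
#' leading block of metabolites — the "carnitine-class" block — is elevated
#' in the two higher-grade groups by the stated fold-changes; all other
#' metabolites are exchangeable across groups (null).
#'
#' @param n_per_group named integer vector, e.g. c(LGG = 8, HGG = 25,
#'   METS = 12); each must be >= 2.
#' @param n_metabolites total metabolites.
#' @param block_size number of elevated "carnitine-class" metabolites.
#' @param fold_changes named fold-change of the block per non-reference
#'   group (reference = first group).
#' @param sdlog lognormal log-scale SD.
#' @param seed integer seed.
#' @return list: matrix (metabolites x samples), groups (factor per
#'   sample), block (metabolite indices), fold_changes.
#' @export
simulate_metabolomics <- function(n_per_group = c(LGG = 8, HGG = 25,
                                                  METS = 12),
                                  n_metabolites = 200, block_size = 15,
                                  fold_changes = c(HGG = 3, METS = 6),
                                  sdlog = 0.5, seed = 1) {
  if (any(n_per_group < 2L))
    stop("each group needs >= 2 samples (Welch t needs a variance)")
  if (block_size > n_metabolites) stop("block larger than matrix")
  groups <- factor(rep(names(n_per_group), times = n_per_group),
                   levels = names(n_per_group))
  with_seed(seed, {
    n_s <- length(groups)
    m <- matrix(rlnorm(n_metabolites * n_s, meanlog = 0, sdlog = sdlog),
                n_metabolites, n_s)
    block <- seq_len(block_size)
    for (g in names(fold_changes)) {
      cols <- which(groups == g)
      m[block, cols] <- m[block, cols] * fold_changes[[g]]
    }
    rownames(m) <- c(sprintf("carnitine_%02d", block),
                     sprintf("metab_%03d", seq_len(n_metabolites -
                                                     block_size)))
    colnames(m) <- paste0(as.character(groups), "_",
                          unlist(lapply(n_per_group, seq_len)))
    list(matrix = m, groups = groups, block = block,
         fold_changes = fold_changes)
  })
}
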