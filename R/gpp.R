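#' Construct a FeatureMatrix
#'
#' @param scores numeric matrix (variants x features) of rank scores in
#'   `[0, 1]`, NA allowed before imputation; columns must be named.
#' @param labels integer/numeric vector, 1 = case, 0 = control, NA =
#'   unlabeled.
#' @param gene gene symbol per variant (recycled if length 1).
#' @param mtr optional raw codon MTR per variant.
#' @param variantId row identifiers.
#' @return a [FeatureMatrix-class].
#' @export
featureMatrix <- function(scores, labels = NA_integer_, gene = "gene",
                          mtr = NA_real_, variantId = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (is.null(variantId)) variantId <- sprintf("v%d", seq_len(n))
  new("FeatureMatrix",
      scores = scores,
      labels = as.integer(rep_len(labels, n)),
      gene = rep_len(as.character(gene), n),
      mtr = as.numeric(rep_len(mtr, n)),
      variantId = as.character(variantId))
}

#' Read a feature matrix from TSV
#'
#' First columns `variant_id`, `gene`, `label` (blank/NA for unlabeled),
#' optionally `mtr`; all remaining columns are feature rank scores.
#'
#' @param path TSV path.
#' @return a [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("variant_id", "gene", "label")
  if (!all(need %in% names(tab))) {
    stop("feature TSV must start with columns: ", paste(need, collapse = ", "))
  }
  mtr <- if ("mtr" %in% names(tab)) tab$mtr else NA_real_
  featCols <- setdiff(names(tab), c(need, "mtr"))
  featureMatrix(as.matrix(tab[, featCols, drop = FALSE]),
                labels = tab$label, gene = tab$gene, mtr = mtr,
                variantId = tab$variant_id)
}

#' Impute missing feature scores by per-gene medians
#'
#' Each missing cell is replaced by the median of the successfully annotated
#' values of that feature among the variants of the same gene. A feature
#' entirely missing within a gene is an error.
#'
#' @param fm a [FeatureMatrix-class].
#' @return the matrix with no missing scores.
#' @export
imputeMissingScores <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  x <- fm@scores
  for (g in unique(fm@gene)) {
    rows <- fm@gene == g
    for (j in seq_len(ncol(x))) {
      miss <- rows & is.na(x[, j])
      if (!any(miss)) next
      vals <- x[rows & !is.na(x[, j]), j]
      if (!length(vals)) {
        stop(sprintf("feature '%s' has no annotated value in gene '%s'",
                     colnames(x)[j], g))
      }
      x[miss, j] <- median(vals)
    }
  }
  fm@scores <- x
  validObject(fm)
  fm
}

#' Prune near-zero-variance features
#'
#' Flags a feature when the ratio of its most common to second most common
#' value exceeds `freqCut` (80/20, i.e. 4) AND its percentage of distinct
#' values out of the number of variants is below `uniqueCut` (5). Delegates
#' to [caret::nearZeroVar()], the reference implementation of this rule.
#'
#' @param fm a [FeatureMatrix-class] (no missing scores).
#' @param freqCut permitted most-common / second-most-common frequency ratio.
#' @param uniqueCut percentage cutoff for distinct values.
#' @return character vector of retained feature names.
#' @export
pruneNearZeroVariance <- function(fm, freqCut = 4, uniqueCut = 5) {
  stopifnot(is(fm, "FeatureMatrix"))
  x <- fm@scores
  drop <- caret::nearZeroVar(x, freqCut = freqCut, uniqueCut = uniqueCut)
  if (length(drop)) colnames(x)[-drop] else colnames(x)
}

#' Prune highly correlated feature pairs
#'
#' While any remaining pair of features has absolute Pearson correlation
#' above `threshold`, removes from the offending pair the member with the
#' larger mean absolute correlation against the currently remaining features,
#' re-evaluating the means after each removal. Delegates to
#' [caret::findCorrelation()] with `exact = TRUE`, which implements exactly
#' this stepwise rule.
#'
#' @param fm a [FeatureMatrix-class] (no missing scores).
#' @param threshold absolute pairwise correlation cutoff (default 0.75).
#' @return character vector of retained feature names.
#' @export
prunePairwiseCorrelated <- function(fm, threshold = 0.75) {
  stopifnot(is(fm, "FeatureMatrix"))
  x <- fm@scores
  if (ncol(x) < 2L) return(colnames(x))
  cm <- cor(x)
  drop <- caret::findCorrelation(cm, cutoff = threshold, exact = TRUE)
  if (length(drop)) colnames(x)[-drop] else colnames(x)
}

boxplotWhiskerMin <- function(z) {
  q <- quantile(z, c(0.25, 0.75), type = 7, names = FALSE)
  lw <- q[1L] - 1.5 * (q[2L] - q[1L])
  min(z[z >= lw])
}

#' Shadow-feature random-forest importance screening
#'
#' Evaluates each feature's ability to discriminate case from control
#' variants against a permutation null, in the style of the Boruta
#' all-relevant scheme. In each of `runs` random-forest runs, every feature
#' is paired with a shadow copy obtained by shuffling its values across
#' variants; the forest's scaled mean-decrease-in-accuracy importance (the
#' Z-score) is recorded for every real feature together with the maximum
#' Z among the shadows.
#'
#' A feature is `informative` when it beats the run-wise max-shadow Z
#' significantly more often than half the time (one-sided binomial test,
#' Bonferroni-corrected across features at `alpha`), `uninformative` when it
#' loses significantly more often, and `inconclusive` otherwise. It is
#' additionally flagged highly informative when its minimum non-outlier Z
#' (boxplot convention, 1.5 x IQR whiskers) exceeds the maximum shadow Z
#' observed across all runs.
#'
#' @param fm a [FeatureMatrix-class] with both classes labeled and no
#'   missing scores.
#' @param seed RNG seed (default 15).
#' @param runs number of random-forest runs (default 1000).
#' @param trees trees per forest (default 500).
#' @param mtry variables tried per split (default 4, capped at the column
#'   count).
#' @param alpha significance level of the binomial hit test.
#' @return a [FeatureImportanceReport-class].
#' @export
assessFeatureImportance <- function(fm, seed = 15L, runs = 1000L,
                                    trees = 500L, mtry = 4L, alpha = 0.05) {
  stopifnot(is(fm, "FeatureMatrix"))
  lab <- !is.na(fm@labels)
  x <- fm@scores[lab, , drop = FALSE]
  y <- factor(fm@labels[lab], levels = c(0L, 1L))
  if (anyNA(x)) stop("impute missing scores before importance assessment")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  k <- ncol(x)
  if (k < 1L) stop("at least one feature is required")
  set.seed(seed)
  z <- matrix(NA_real_, nrow = runs, ncol = k,
              dimnames = list(NULL, colnames(x)))
  shadowMax <- numeric(runs)
  for (r in seq_len(runs)) {
    shadow <- apply(x, 2L, sample)
    colnames(shadow) <- paste0(".shadow.", colnames(x))
    xs <- cbind(x, shadow)
    rf <- randomForest::randomForest(
      x = xs, y = y, ntree = trees, mtry = min(mtry, ncol(xs)),
      importance = TRUE)
    imp <- randomForest::importance(rf, type = 1L, scale = TRUE)[, 1L]
    z[r, ] <- imp[colnames(x)]
    shadowMax[r] <- max(imp[colnames(shadow)])
  }
  hits <- colSums(z > shadowMax)
  pBeat <- pbinom(hits - 1L, runs, 0.5, lower.tail = FALSE)
  pLose <- pbinom(hits, runs, 0.5)
  category <- ifelse(pmin(1, pBeat * k) < alpha, "informative",
                     ifelse(pmin(1, pLose * k) < alpha, "uninformative",
                            "inconclusive"))
  whiskerMin <- apply(z, 2L, boxplotWhiskerMin)
  highly <- category == "informative" & whiskerMin > max(shadowMax)
  new("FeatureImportanceReport",
      zScores = z, shadowMax = shadowMax, hits = as.integer(hits),
      category = factor(category,
                        levels = c("uninformative", "inconclusive",
                                   "informative")),
      highlyInformative = unname(highly),
      params = list(seed = seed, runs = runs, trees = trees, mtry = mtry,
                    alpha = alpha))
}

# Ridge-penalized logistic fit by IRLS; used when the ordinary ML fit runs
# into complete separation. Intercept unpenalized. Returns the unpenalized
# log-likelihood at the penalized estimates for AIC bookkeeping.
ridgeLogistic <- function(X, y, lambda = 1e-3, maxit = 200L, tol = 1e-9) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xi, Xi * w) + 2 * diag(pen, p)
    g <- crossprod(Xi, y - mu) - 2 * pen * beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  mu <- plogis(drop(Xi %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(coef = setNames(drop(beta), colnames(Xi)),
       aic = -2 * ll + 2 * p, separation = TRUE)
}

fitLogistic <- function(X, y, preds, ridgeLambda = 1e-3) {
  if (!length(preds)) {
    fit <- glm(y ~ 1, family = binomial())
    return(list(coef = coef(fit), aic = AIC(fit), separation = FALSE))
  }
  dat <- data.frame(y = y, X[, preds, drop = FALSE], check.names = FALSE)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep) {
    return(ridgeLogistic(as.matrix(X[, preds, drop = FALSE]), y,
                         lambda = ridgeLambda))
  }
  list(coef = coef(fit), aic = AIC(fit), separation = FALSE)
}

#' Forward-backward AIC stepwise selection of a gene-specific logistic model
#'
#' Fits `logit Pr(Y = 1) = b0 + b1 X1 + ... + bi Xi` over candidate features
#' taken in importance order. Starting from the raw codon MTR (when
#' `includeMtr`) or the intercept-only model, each candidate is accepted only
#' when the relative Akaike likelihood of the incumbent versus the candidate,
#' `exp((AIC_new - AIC_old) / 2)`, is at most `stopAlpha` — i.e. the larger
#' model must make the incumbent implausible. Selection halts at the first
#' rejected candidate. After each acceptance every included feature is
#' re-tested for removal under the same criterion.
#'
#' Complete separation (possible in small training sets) is detected and the
#' affected fit falls back to a weakly ridge-penalized likelihood, noted in
#' the trace.
#'
#' @param fm a [FeatureMatrix-class] with labels and no missing scores.
#' @param rankedFeatures candidate feature names, ordered by importance.
#' @param includeMtr start the model from the raw codon MTR (applies when
#'   the gene passed the MTR enrichment screen).
#' @param stopAlpha relative-likelihood acceptance threshold (default 0.05).
#' @param geneSymbol label for the fitted model (default: the matrix's gene,
#'   or `"global"` when pooled over several).
#' @param ridgeLambda ridge penalty used by the separation fallback.
#' @return a [GeneModel-class].
#' @export
selectGeneModel <- function(fm, rankedFeatures, includeMtr = FALSE,
                            stopAlpha = 0.05, geneSymbol = NULL,
                            ridgeLambda = 1e-3) {
  stopifnot(is(fm, "FeatureMatrix"))
  lab <- !is.na(fm@labels)
  y <- fm@labels[lab]
  if (length(unique(y)) < 2L) stop("both classes must be present to fit")
  X <- as.data.frame(fm@scores[lab, , drop = FALSE])
  if (includeMtr) {
    if (anyNA(fm@mtr[lab])) stop("MTR values are missing for labeled variants")
    X$MTR <- fm@mtr[lab]
  }
  rankedFeatures <- setdiff(rankedFeatures, "MTR")
  if (!all(rankedFeatures %in% colnames(X))) {
    stop("unknown candidate feature(s): ",
         paste(setdiff(rankedFeatures, colnames(X)), collapse = ", "))
  }
  if (is.null(geneSymbol)) {
    g <- unique(fm@gene[lab])
    geneSymbol <- if (length(g) == 1L) g else "global"
  }

  trace <- data.frame(step = integer(0), action = character(0),
                      feature = character(0), aic = numeric(0),
                      accepted = logical(0), note = character(0),
                      stringsAsFactors = FALSE)
  addTrace <- function(step, action, feature, aic, accepted, note = "") {
    trace[nrow(trace) + 1L, ] <<- list(step, action, feature, aic, accepted,
                                       note)
  }

  preds <- if (includeMtr) "MTR" else character(0)
  inc <- fitLogistic(X, y, preds, ridgeLambda)
  addTrace(0L, "start", if (includeMtr) "MTR" else "(intercept)", inc$aic,
           TRUE, if (inc$separation) "ridge fallback" else "")
  step <- 0L
  accThreshold <- 2 * log(stopAlpha)  # accept iff AIC_new - AIC_old <= this

  for (f in rankedFeatures) {
    if (f %in% preds) next
    step <- step + 1L
    cand <- fitLogistic(X, y, c(preds, f), ridgeLambda)
    if (cand$aic - inc$aic <= accThreshold) {
      preds <- c(preds, f)
      inc <- cand
      addTrace(step, "add", f, cand$aic, TRUE,
               if (cand$separation) "ridge fallback" else "")
      # backward pass: drop any feature whose removal now improves enough
      repeat {
        removed <- FALSE
        for (g in preds) {
          red <- fitLogistic(X, y, setdiff(preds, g), ridgeLambda)
          if (red$aic - inc$aic <= accThreshold) {
            preds <- setdiff(preds, g)
            inc <- red
            step <- step + 1L
            addTrace(step, "remove", g, red$aic, TRUE,
                     if (red$separation) "ridge fallback" else "")
            removed <- TRUE
            break
          }
        }
        if (!removed) break
      }
    } else {
      addTrace(step, "add", f, cand$aic, FALSE, "stop rule")
      break
    }
  }

  cf <- inc$coef
  intercept <- unname(cf[["(Intercept)"]])
  betas <- cf[setdiff(names(cf), "(Intercept)")]
  model <- new("GeneModel", geneSymbol = geneSymbol, intercept = intercept,
               coefficients = betas, trace = trace, trainingAuc = NA_real_)
  scores <- scoreGpp(model, X)
  model@trainingAuc <- evaluateAuc(scores, y)
  model
}

#' Score variants with a gene-specific pathogenicity model
#'
#' Inverse-logit of the fitted linear predictor: the gene-specific
#' probability of pathogenicity (GPP) of each variant, strictly inside
#' (0, 1).
#'
#' @param model a [GeneModel-class].
#' @param features data.frame or matrix containing a column for every model
#'   feature (including `MTR` when the model uses it).
#' @return numeric vector of GPP scores.
#' @export
scoreGpp <- function(model, features) {
  stopifnot(is(model, "GeneModel"))
  features <- as.data.frame(features)
  need <- names(model@coefficients)
  missing <- setdiff(need, colnames(features))
  if (length(missing)) {
    stop("variant features missing from input: ", paste(missing, collapse = ", "))
  }
  if (length(need)) {
    xm <- as.matrix(features[, need, drop = FALSE])
    if (anyNA(xm)) stop("missing feature value for a scored variant")
    eta <- model@intercept + drop(xm %*% model@coefficients)
  } else {
    eta <- rep(model@intercept, nrow(features))
  }
  plogis(eta)
}

#' Rank-based area under the ROC curve
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counting one half — the Mann-Whitney U statistic
#' divided by the number of case-control pairs.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
evaluateAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write a fitted gene model to JSON
#'
#' @param model a [GeneModel-class].
#' @param path output JSON path.
#' @export
writeGeneModel <- function(model, path) {
  stopifnot(is(model, "GeneModel"))
  out <- list(
    gene_symbol = model@geneSymbol,
    intercept = model@intercept,
    coefficients = as.list(model@coefficients),
    training_auc = model@trainingAuc,
    trace = model@trace)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(out)
}
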