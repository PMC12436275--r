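# Activity labelling and the random-forest regression QSAR model.

#' Assign pX labels and sample weights to raw activity rows
#'
#' Rows without a defined pX (or flagged inactive in the activity comment)
#' receive the placeholder pX of 3.99 -- just below the inactive boundary of
#' 4 -- and a down-weight of 0.1, so the forest learns to predict negative
#' samples without letting them dominate. Rows at or above the bioactivity
#' threshold (pX 6.5 by default) are positives with weight 1.0; defined but
#' sub-threshold rows keep their pX at weight 0.1. Replicate measurements of
#' the same compound-target pair are aggregated by the mean of their defined
#' pX values.
#'
#' @param records data.frame with columns `compound_id`, `smiles`,
#'   `target_id`, `px` (numeric, NA when undefined) and optionally `comment`,
#'   `standard_type`, `standard_relation`.
#' @param activityThreshold pX at or above which a record is a positive
#'   (default 6.5).
#' @param inactivePx placeholder pX for undefined/inactive rows (default 3.99).
#' @return data.frame with one row per compound-target pair and columns
#'   `compound_id`, `smiles`, `target_id`, `px`, `sample_weight`; the number
#'   of rows dropped for missing SMILES is attached as attribute
#'   `dropped_no_smiles`.
#' @export
assignPxLabels <- function(records, activityThreshold = 6.5,
                           inactivePx = 3.99) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "smiles", "target_id", "px") %in%
                  names(records)))
  noSmiles <- is.na(records$smiles) | !nzchar(records$smiles)
  dropped <- sum(noSmiles)
  if (dropped > 0L)
    message(sprintf("dropped %d record(s) without SMILES", dropped))
  records <- records[!noSmiles, , drop = FALSE]
  px <- as.numeric(records$px)
  if ("comment" %in% names(records)) {
    inactive <- !is.na(records$comment) &
      grepl("not active|inactive", records$comment, ignore.case = TRUE)
    px[inactive] <- NA_real_
  }
  key <- paste(records$compound_id, records$target_id, sep = "\r")
  agg <- lapply(split(seq_along(key), key), function(ii) {
    pxi <- px[ii]
    def <- pxi[is.finite(pxi)]
    val <- if (length(def)) mean(def) else inactivePx
    list(i = ii[1], px = val, defined = length(def) > 0L)
  })
  first <- vapply(agg, `[[`, numeric(1), "i")
  pxOut <- vapply(agg, `[[`, numeric(1), "px")
  defined <- vapply(agg, `[[`, logical(1), "defined")
  weight <- ifelse(defined & pxOut >= activityThreshold, 1.0, 0.1)
  out <- data.frame(compound_id = records$compound_id[first],
                    smiles = records$smiles[first],
                    target_id = records$target_id[first],
                    px = pxOut,
                    sample_weight = weight,
                    stringsAsFactors = FALSE)
  out <- out[order(first), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_no_smiles") <- dropped
  out
}

#' Train the random-forest regression QSAR model
#'
#' Featurizes the labelled records ([featurize()]), fits the min-max scaler,
#' and grows a 1000-tree regression forest (variance-reduction splitting)
#' with the 1.0/0.1 sample weights applied as case weights. The out-of-bag
#' R squared is logged and stored on the model.
#'
#' @param records labelled data.frame from [assignPxLabels()].
#' @param numTrees number of trees (default 1000).
#' @param mtry number of candidate features per split; default NULL uses the
#'   forest library's default (the square root of the feature count), which
#'   recovers the synthetic structure-activity law well at a fraction of the
#'   cost of denser splits.
#' @param seed integer seed; the same seed reproduces the same forest.
#' @param targetId stored on the model; defaults to the records' target.
#' @return a [QsarModel-class].
#' @export
trainQsar <- function(records, numTrees = 1000L, mtry = NULL, seed = 1L,
                      targetId = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 20L)
  if (length(unique(records$sample_weight)) < 2L)
    warning("only one sample-weight class present in the training set")
  if (is.null(targetId)) targetId <- as.character(records$target_id[1])
  x <- featurize(records$smiles)
  scaler <- fitScaler(x)
  xs <- applyScaler(x, scaler)
  if (length(unique(records$px)) == 1L)
    warning("all training labels identical; the forest will be constant")
  df <- as.data.frame(xs)
  df$.px <- records$px
  args <- list(
    dependent.variable.name = ".px", data = df,
    num.trees = numTrees,
    case.weights = records$sample_weight,
    seed = seed, num.threads = 1L, oob.error = TRUE, verbose = FALSE)
  if (!is.null(mtry)) args$mtry <- mtry
  fit <- do.call(ranger::ranger, args)
  oobR2 <- 1 - fit$prediction.error / stats::var(records$px)
  message(sprintf("QSAR forest for %s: OOB R2 = %.3f", targetId, oobR2))
  new("QsarModel", forest = fit, scaler = scaler,
      targetId = targetId, seed = as.integer(seed), oobR2 = oobR2)
}

#' Predict pX for a batch of SMILES
#'
#' Invalid SMILES are marked `NA` (never an error); downstream reward code
#' treats them as invalid molecules. Inputs are canonicalized before
#' featurization, so equivalent renderings of the same molecule receive the
#' same prediction.
#'
#' @param model a [QsarModel-class].
#' @param smiles character vector.
#' @return numeric vector of predicted pX, `NA` where the SMILES is invalid.
#' @export
predictPx <- function(model, smiles) {
  stopifnot(is(model, "QsarModel"))
  out <- rep(NA_real_, length(smiles))
  ok <- isValidSmiles(smiles)
  if (any(ok)) {
    x <- featurize(smiles[ok])
    xs <- applyScaler(x, model@scaler)
    pred <- stats::predict(model@forest, data = as.data.frame(xs),
                           num.threads = 1L)$predictions
    out[ok] <- pred
  }
  out
}

#' k-fold cross-validation of the QSAR protocol
#'
#' Utility for judging a feature/forest configuration: splits the records
#' into folds, trains on k-1 and predicts the held-out fold.
#'
#' @param records labelled data.frame from [assignPxLabels()].
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment and forests.
#' @param ... passed to [trainQsar()].
#' @return list with `r2` (overall held-out R squared) and `predictions`
#'   (numeric vector aligned with `records`).
#' @export
crossValidateQsar <- function(records, k = 5L, seed = 1L, ...) {
  n <- nrow(records)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- records[fold != f, , drop = FALSE]
    m <- trainQsar(tr, seed = seed, ...)
    pred[fold == f] <- predictPx(m, records$smiles[fold == f])
  }
  ss <- sum((records$px - pred)^2)
  r2 <- 1 - ss / sum((records$px - mean(records$px))^2)
  list(r2 = r2, predictions = pred)
}

#' Read / write ligand activity tables
#'
#' CSV with header `compound_id,smiles,target_id,px,comment,standard_type,
#' standard_relation`; `px` may be empty for undefined activities.
#'
#' @param path file path.
#' @param records data.frame to write.
#' @return `readLigandTable` a data.frame; the writer returns its input
#'   invisibly.
#' @export
readLigandTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(px = "numeric"))
  need <- c("compound_id", "smiles", "target_id", "px")
  if (!all(need %in% names(df)))
    stop("ligand table must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname readLigandTable
#' @export
writeLigandTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(records)
}

#' Save / load a QSAR model artifact
#'
#' One file holding the forest, the scaler and the metadata (target, feature
#' order, seed).
#'
#' @param model a [QsarModel-class].
#' @param path file path.
#' @return `loadQsarModel` the model; the writer returns its input invisibly.
#' @export
saveQsarModel <- function(model, path) {
  saveRDS(list(forest = model@forest, scaler = model@scaler,
               targetId = model@targetId, seed = model@seed,
               oobR2 = model@oobR2, features = featureNames()), path)
  invisible(model)
}

#' @rdname saveQsarModel
#' @export
loadQsarModel <- function(path) {
  x <- readRDS(path)
  new("QsarModel", forest = x$forest, scaler = x$scaler,
      targetId = x$targetId, seed = x$seed, oobR2 = x$oobR2)
}
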