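#' @import methods
NULL

#' Vocabulary of SMILES tokens
#'
#' An ordered set of unique SMILES tokens with the two control tokens
#' \code{GO} (sequence start) and \code{EOS} (sequence end). Token order is the
#' model's index space, so it is kept stable: control tokens first, then all
#' observed tokens in radix (locale-independent) sort order.
#'
#' @slot tokens character vector of unique tokens; \code{tokens[1] == "GO"},
#'   \code{tokens[2] == "EOS"}.
#' @export
setClass("Vocabulary", representation(tokens = "character"))

setValidity("Vocabulary", function(object) {
  tk <- object@tokens
  if (anyDuplicated(tk)) return("tokens must be unique")
  if (sum(tk == "GO") != 1L || sum(tk == "EOS") != 1L)
    return("GO and EOS must each occur exactly once")
  TRUE
})

#' Recurrent SMILES generator
#'
#' A SMILES language model: token embedding, one or more stacked LSTM blocks
#' joined by a rectifier and a learned projection back to the embedding width,
#' causal multi-head self-attention over the final block's outputs, and a
#' linear layer to vocabulary logits. Parameters are plain numeric matrices
#' (trained by the compiled backpropagation core), so checkpoints are ordinary
#' R objects.
#'
#' @slot config named list, see [generatorConfig()].
#' @slot params named list of weight matrices/vectors.
#' @slot vocab a [Vocabulary-class] object.
#' @export
setClass("SmilesGenerator",
         representation(config = "list", params = "list", vocab = "Vocabulary"))

setValidity("SmilesGenerator", function(object) {
  cfg <- object@config
  if (cfg$vocab_size != length(object@vocab@tokens))
    return("config vocab_size does not match vocabulary")
  if (cfg$attention_heads * cfg$key_dim != cfg$hidden_size)
    return("attention_heads * key_dim must equal hidden_size")
  TRUE
})

#' Random-forest QSAR activity model
#'
#' A regression random forest over 2067-dimensional molecular features
#' (2048 folded ECFP6 bits + 19 physicochemical descriptors), together with
#' the min-max scaler fitted on its training set. Predicts pX
#' (\eqn{-\log_{10}} activity) for arbitrary SMILES.
#'
#' @slot forest fitted \pkg{ranger} forest.
#' @slot scaler list with per-feature \code{lo} and \code{hi} bounds.
#' @slot targetId character, identifier of the biological target.
#' @slot seed integer seed used at fit time.
#' @slot oobR2 numeric, out-of-bag R squared logged at fit time.
#' @export
setClass("QsarModel",
         representation(forest = "ANY", scaler = "list", targetId = "character",
                        seed = "integer", oobR2 = "numeric"))

#' One design objective
#'
#' Couples an activity predictor with an affinity direction and the reward
#' threshold \eqn{t_j} used by desirability and by the Pareto score clipping.
#' The predictor is either a [QsarModel-class] or any function mapping a
#' character vector of SMILES to numeric pX values (toy objectives in tests
#' use simple substructure-count functions).
#'
#' @slot targetId character.
#' @slot direction \code{"high_affinity"} or \code{"low_affinity"}.
#' @slot threshold numeric in (0,1); default 0.5, i.e. pX 6.5 under the
#'   fixed [4,9] normalization.
#' @slot predictor function or [QsarModel-class].
#' @export
setClass("ObjectiveSpec",
         representation(targetId = "character", direction = "character",
                        threshold = "numeric", predictor = "ANY"))

setValidity("ObjectiveSpec", function(object) {
  if (!object@direction %in% c("high_affinity", "low_affinity"))
    return("direction must be 'high_affinity' or 'low_affinity'")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must lie strictly inside (0,1)")
  TRUE
})

#' @describeIn ObjectiveSpec-class constructor.
#' @param targetId,direction,threshold,predictor see slots.
#' @export
objectiveSpec <- function(targetId, direction = c("high_affinity", "low_affinity"),
                          threshold = 0.5, predictor = NULL) {
  direction <- match.arg(direction)
  new("ObjectiveSpec", targetId = targetId, direction = direction,
      threshold = threshold, predictor = predictor)
}

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary of %d tokens (GO at %d, EOS at %d)\n",
              length(object@tokens), goIndex(object), eosIndex(object)))
  cat("  ", paste(utils::head(object@tokens, 12L), collapse = " "),
      if (length(object@tokens) > 12L) "..." else "", "\n")
})

setMethod("show", "SmilesGenerator", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("SmilesGenerator: vocab %d, embed %d, %d block(s) x %d LSTM ",
                     "layer(s), hidden %d, %d attention head(s) (d_k %d)\n"),
              cfg$vocab_size, cfg$embed_dim, cfg$num_blocks, cfg$block_layers,
              cfg$hidden_size, cfg$attention_heads, cfg$key_dim))
})

setMethod("show", "QsarModel", function(object) {
  cat(sprintf("QsarModel for %s: %d trees, OOB R2 = %.3f\n",
              object@targetId, object@forest$num.trees, object@oobR2))
})

setMethod("show", "ObjectiveSpec", function(object) {
  cat(sprintf("Objective %s: %s, threshold %.2f\n",
              object@targetId, object@direction, object@threshold))
})
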