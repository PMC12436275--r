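#' Vocabulary accessors
#'
#' @param x a [Vocabulary-class].
#' @return `vocabTokens` the token vector; `vocabSize` its length;
#'   `goIndex`/`eosIndex` the 1-based positions of the control tokens.
#' @export
setGeneric("vocabTokens", function(x) standardGeneric("vocabTokens"))
#' @rdname vocabTokens
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))
#' @rdname vocabTokens
#' @export
setGeneric("goIndex", function(x) standardGeneric("goIndex"))
#' @rdname vocabTokens
#' @export
setGeneric("eosIndex", function(x) standardGeneric("eosIndex"))

#' @rdname vocabTokens
setMethod("vocabTokens", "Vocabulary", function(x) x@tokens)
#' @rdname vocabTokens
setMethod("vocabSize", "Vocabulary", function(x) length(x@tokens))
#' @rdname vocabTokens
setMethod("goIndex", "Vocabulary", function(x) match("GO", x@tokens))
#' @rdname vocabTokens
setMethod("eosIndex", "Vocabulary", function(x) match("EOS", x@tokens))

#' Generator accessors
#'
#' @param x a [SmilesGenerator-class].
#' @return `generatorVocab` the vocabulary; `generatorParams` the named list of
#'   weights; `generatorConfigOf` the configuration list.
#' @export
setGeneric("generatorVocab", function(x) standardGeneric("generatorVocab"))
#' @rdname generatorVocab
#' @export
setGeneric("generatorParams", function(x) standardGeneric("generatorParams"))
#' @rdname generatorVocab
#' @export
setGeneric("generatorConfigOf", function(x) standardGeneric("generatorConfigOf"))

#' @rdname generatorVocab
setMethod("generatorVocab", "SmilesGenerator", function(x) x@vocab)
#' @rdname generatorVocab
setMethod("generatorParams", "SmilesGenerator", function(x) x@params)
#' @rdname generatorVocab
setMethod("generatorConfigOf", "SmilesGenerator", function(x) x@config)
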