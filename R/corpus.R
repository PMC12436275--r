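# SMILES preprocessing, tokenization, vocabulary and sequence coding.

# Elements allowed in "organic" molecules; anything else counts as a metal /
# exotic atom and the molecule is rejected during standardization.
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                       "Se", "Br", "I")

# Valence electrons per neutral atom, used by the descriptor block.
.VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4,
                        P = 5, S = 6, Cl = 7, Se = 6, Br = 7, I = 7)

# Token alternation, longest-first. Bracket atoms and %nn ring closures are
# atomic; two-letter organic-subset halogens likewise.
.SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]+\\]",             # bracket atom
  "|%[0-9]{2}",                # two-digit ring closure
  "|Cl|Br",                    # two-letter halogens
  "|[BCNOPSFI]",               # organic-subset atoms
  "|[bcnops]",                 # aromatic atoms
  "|[0-9]",                    # ring closures
  "|[=#$:/\\\\.()+-]"          # bonds, branches, dot, (unbracketed charge)
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into atom-level tokens. Bracket expressions
#' (`[nH]`, `[O-]`, ...), two-letter halogens (`Cl`, `Br`) and `%nn` ring
#' closures are single tokens, so that concatenating the tokens always
#' reproduces the input exactly.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @examples
#' tokenizeSmiles("c1cc[nH]c1")
#' @export
tokenizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  m <- gregexpr(.SMILES_TOKEN_RE, smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    # locate the first character not claimed by any token
    covered <- rep(FALSE, nchar(smiles))
    if (m[1] != -1L)
      for (i in seq_along(m))
        covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
    pos <- which(!covered)[1]
    bad <- substr(smiles, pos, pos)
    if (bad == "[")
      stop(sprintf("unmatched bracket at position %d in '%s'", pos, smiles))
    stop(sprintf("unrecognized character '%s' at position %d in '%s'",
                 bad, pos, smiles))
  }
  toks
}

# Parse a bracket-atom token into its parts. Returns NULL if unparseable.
.parseBracket <- function(tok) {
  m <- regexec(paste0(
    "^\\[([0-9]*)",                          # isotope
    "([A-Z][a-z]?|[a-z]{1,2}|\\*)",          # element (aromatic lowercase)
    "(@{1,2}|@TH[12]|@AL[12]|@SP[1-3])?",    # chirality
    "(H[0-9]*)?",                            # explicit hydrogens
    "(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?",  # charge
    "(?::([0-9]+))?\\]$"), tok, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  g <- regmatches(tok, list(m))[[1]]
  hRaw <- g[5]
  hcount <- if (!nzchar(hRaw)) 0L else if (hRaw == "H") 1L else
    as.integer(sub("^H", "", hRaw))
  chgRaw <- g[6]
  charge <- 0L
  if (nzchar(chgRaw)) {
    charge <- if (grepl("^[+-][0-9]+$", chgRaw)) as.integer(chgRaw) else
      nchar(chgRaw) * (if (substr(chgRaw, 1, 1) == "+") 1L else -1L)
  }
  list(isotope = g[2], element = g[3], chirality = g[4],
       hcount = hcount, charge = charge, map = g[7])
}

.renderBracket <- function(p) {
  h <- if (p$hcount == 0L) "" else if (p$hcount == 1L) "H" else
    paste0("H", p$hcount)
  ch <- if (p$charge == 0L) "" else if (p$charge == 1L) "+" else
    if (p$charge == -1L) "-" else sprintf("%+d", p$charge)
  paste0("[", p$isotope, p$element, p$chirality, h, ch,
         if (nzchar(p$map)) paste0(":", p$map) else "", "]")
}

# Element symbol of an atom token, or NA for non-atom tokens.
.tokenElement <- function(tok) {
  if (grepl("^\\[", tok)) {
    p <- .parseBracket(tok)
    if (is.null(p)) return(NA_character_)
    el <- p$element
    if (el == "*") return("*")
    return(paste0(toupper(substr(el, 1, 1)), substr(el, 2, nchar(el))))
  }
  if (tok %in% c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br"))
    return(tok)
  if (tok %in% c("b", "c", "n", "o", "p", "s")) return(toupper(tok))
  NA_character_
}

# Count heavy (non-hydrogen) atoms in a token vector.
.heavyAtomCount <- function(toks) {
  els <- vapply(toks, .tokenElement, character(1), USE.NAMES = FALSE)
  sum(!is.na(els) & els != "H")
}

# Simple hydrogen-shift neutralization at the token level: protonated atoms
# lose H+ down to neutral, deprotonated atoms gain H. Charges that cannot be
# neutralized this way (e.g. quaternary N+) are kept.
.neutralizeTokens <- function(toks) {
  vapply(toks, function(tok) {
    if (!grepl("^\\[", tok)) return(tok)
    p <- .parseBracket(tok)
    if (is.null(p) || p$charge == 0L) return(tok)
    if (p$charge > 0L && p$hcount >= p$charge) {
      p$hcount <- p$hcount - p$charge
      p$charge <- 0L
    } else if (p$charge < 0L) {
      p$hcount <- p$hcount - p$charge
      p$charge <- 0L
    }
    .renderBracket(p)
  }, character(1), USE.NAMES = FALSE)
}

# Structural syntax checks the lenient chemistry backend does not perform:
# balanced branches, paired ring-bond digits, non-empty branches.
.syntaxOk <- function(toks) {
  depth <- 0L
  open <- character(0)
  prev <- ""
  for (tok in toks) {
    if (tok == "(") {
      depth <- depth + 1L
    } else if (tok == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
      if (prev == "(") return(FALSE)
    } else if (grepl("^[0-9]$|^%[0-9]{2}$", tok)) {
      id <- sub("^%", "", tok)
      if (id %in% open) open <- setdiff(open, id) else open <- c(open, id)
    }
    prev <- tok
  }
  depth == 0L && length(open) == 0L
}

# Batched OpenBabel canonicalization through the obabel CLI (with -e, so one
# hopeless molecule does not abort the rest of the batch, unlike the
# in-process conversion stream). Returns a character vector aligned with the
# input; NA where OpenBabel failed to parse. Input lines are tagged with
# their index so dropped molecules can be identified.
.canonicalizeBatch <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  f <- tempfile(fileext = ".smi")
  on.exit(unlink(f))
  writeLines(paste0(smiles, " mfid", seq_len(n)), f)
  out <- suppressWarnings(
    system2("obabel", c(shQuote(f), "-ocan", "-e"),
            stdout = TRUE, stderr = FALSE))
  res <- rep(NA_character_, n)
  parts <- strsplit(out, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2L) {
      id <- trimws(p[2])
      if (grepl("^mfid[0-9]+$", id) && nzchar(p[1]))
        res[as.integer(sub("^mfid", "", id))] <- p[1]
    }
  }
  res
}

#' Standardize a SMILES string
#'
#' Charge-standardizes a molecule the way large activity databases are
#' cleaned before modelling: keep the largest organic fragment (dropping
#' counter-ions), neutralize charges by hydrogen shifts where possible,
#' reject molecules containing metals or falling outside heavy-atom size
#' bounds, and return the canonical SMILES of what remains. Failures are
#' reported as a reason code, never as an error.
#'
#' @param smiles character vector of SMILES strings.
#' @param minHeavy,maxHeavy inclusive heavy-atom bounds for the retained
#'   fragment (defaults 5 and 100, covering drug-like space).
#' @return a data.frame with columns `smiles` (input), `canonical` (NA on
#'   rejection) and `reason` (`""`, `"unparseable"`, `"metal"`, `"too_small"`
#'   or `"too_large"`).
#' @examples
#' standardizeMolecule("CC(=O)[O-].[Na+]")
#' @export
standardizeMolecule <- function(smiles, minHeavy = 5L, maxHeavy = 100L) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  canonical <- rep(NA_character_, n)
  reason <- rep("unparseable", n)
  cleaned <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) next
    toks <- tryCatch(tokenizeSmiles(s), error = function(e) NULL)
    if (is.null(toks) || !.syntaxOk(toks)) next
    # split into fragments on '.', keep the largest organic one
    idx <- which(toks == ".")
    bounds <- c(0L, idx, length(toks) + 1L)
    frags <- lapply(seq_len(length(bounds) - 1L), function(k) {
      lo <- bounds[k] + 1L; hi <- bounds[k + 1L] - 1L
      if (lo > hi) character(0) else toks[lo:hi]
    })
    frags <- Filter(length, frags)
    if (!length(frags)) next
    organic <- vapply(frags, function(f) {
      els <- vapply(f, .tokenElement, character(1), USE.NAMES = FALSE)
      any(!is.na(els) & els == "C")
    }, logical(1))
    cand <- if (any(organic)) frags[organic] else frags
    sizes <- vapply(cand, .heavyAtomCount, integer(1))
    frag <- cand[[which.max(sizes)]]
    # metal / exotic atom check on the retained fragment
    els <- vapply(frag, .tokenElement, character(1), USE.NAMES = FALSE)
    els <- els[!is.na(els)]
    if (any(!els %in% .ORGANIC_ELEMENTS)) {
      reason[i] <- "metal"
      next
    }
    frag <- .neutralizeTokens(frag)
    cleaned[i] <- paste(frag, collapse = "")
    reason[i] <- ""
  }

  todo <- which(reason == "" & !is.na(cleaned))
  if (length(todo)) {
    can <- .canonicalizeBatch(cleaned[todo])
    for (k in seq_along(todo)) {
      i <- todo[k]
      if (is.na(can[k])) {
        reason[i] <- "unparseable"
        next
      }
      nh <- .heavyAtomCount(tokenizeSmiles(can[k]))
      if (nh < minHeavy) {
        reason[i] <- "too_small"
      } else if (nh > maxHeavy) {
        reason[i] <- "too_large"
      } else {
        canonical[i] <- can[k]
      }
    }
  }
  data.frame(smiles = smiles, canonical = canonical, reason = reason,
             stringsAsFactors = FALSE)
}

#' Standardize and deduplicate a compound set
#'
#' Applies [standardizeMolecule()] to every record, removes records whose
#' canonical SMILES duplicates an earlier one, and returns both the retained
#' set and a per-reason rejection log. Filtering is idempotent.
#'
#' @param compounds data.frame with columns `source_id` and `smiles`.
#' @param minHeavy,maxHeavy heavy-atom bounds, see [standardizeMolecule()].
#' @return list with `retained` (columns `source_id`, `smiles` canonical) and
#'   `rejected` (columns `source_id`, `smiles`, `reason`).
#' @export
filterDataset <- function(compounds, minHeavy = 5L, maxHeavy = 100L) {
  stopifnot(is.data.frame(compounds),
            all(c("source_id", "smiles") %in% names(compounds)))
  if (nrow(compounds) == 0L) {
    return(list(retained = data.frame(source_id = character(0),
                                      smiles = character(0),
                                      stringsAsFactors = FALSE),
                rejected = data.frame(source_id = character(0),
                                      smiles = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)))
  }
  std <- standardizeMolecule(compounds$smiles, minHeavy, maxHeavy)
  reason <- std$reason
  keep <- reason == "" & !is.na(std$canonical)
  dup <- duplicated(std$canonical) & keep
  reason[dup] <- "duplicate"
  keep <- keep & !dup
  list(
    retained = data.frame(source_id = compounds$source_id[keep],
                          smiles = std$canonical[keep],
                          stringsAsFactors = FALSE),
    rejected = data.frame(source_id = compounds$source_id[!keep],
                          smiles = compounds$smiles[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE)
  )
}

#' Build a vocabulary from a token corpus
#'
#' Collects every token observed in the corpus and prepends the control
#' tokens. Ordering is deterministic (GO, EOS, then radix-sorted tokens), so
#' the same corpus always yields the same vocabulary file.
#'
#' @param corpus list of token vectors (from [tokenizeSmiles()]), or a
#'   character vector of SMILES which will be tokenized.
#' @return a [Vocabulary-class].
#' @export
buildVocabulary <- function(corpus) {
  if (is.character(corpus)) corpus <- lapply(corpus, tokenizeSmiles)
  if (!length(corpus)) stop("empty corpus")
  toks <- sort(unique(unlist(corpus, use.names = FALSE)), method = "radix")
  toks <- setdiff(toks, c("GO", "EOS"))
  new("Vocabulary", tokens = c("GO", "EOS", toks))
}

#' Encode a SMILES string as vocabulary indices
#'
#' Tokenizes and maps tokens to 1-based vocabulary indices, appending EOS.
#' Out-of-vocabulary tokens are an error naming the token.
#'
#' @param smiles single SMILES string.
#' @param vocab a [Vocabulary-class].
#' @return integer vector of indices ending with the EOS index.
#' @export
encodeSmiles <- function(smiles, vocab) {
  toks <- tokenizeSmiles(smiles)
  idx <- match(toks, vocab@tokens)
  if (anyNA(idx)) {
    bad <- toks[which(is.na(idx))[1]]
    stop(sprintf("token '%s' not in vocabulary", bad))
  }
  c(idx, eosIndex(vocab))
}

#' Decode vocabulary indices back to a SMILES string
#'
#' Stops at the first EOS; a leading GO is skipped.
#'
#' @param indices integer vector of vocabulary indices.
#' @param vocab a [Vocabulary-class].
#' @return SMILES string.
#' @export
decodeSmiles <- function(indices, vocab) {
  if (!length(indices)) return("")
  if (any(indices < 1L | indices > length(vocab@tokens)))
    stop("index out of vocabulary range")
  if (indices[1] == goIndex(vocab)) indices <- indices[-1]
  stopAt <- which(indices == eosIndex(vocab))
  if (length(stopAt)) indices <- indices[seq_len(stopAt[1] - 1L)]
  paste(vocab@tokens[indices], collapse = "")
}

#' Read / write corpus and vocabulary files
#'
#' Corpus files hold one SMILES per line; vocabulary files one token per line
#' (line number = index).
#'
#' @param path file path.
#' @param smiles character vector of SMILES.
#' @param vocab a [Vocabulary-class].
#' @return `readSmilesFile` a character vector; `readVocabulary` a
#'   [Vocabulary-class]; the writers return their input invisibly.
#' @export
readSmilesFile <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(x)]
}

#' @rdname readSmilesFile
#' @export
writeSmilesFile <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(smiles)
}

#' @rdname readSmilesFile
#' @export
readVocabulary <- function(path) {
  new("Vocabulary", tokens = readLines(path, warn = FALSE))
}

#' @rdname readSmilesFile
#' @export
writeVocabulary <- function(vocab, path) {
  writeLines(vocab@tokens, path)
  invisible(vocab)
}

#' Syntactic + chemical validity of SMILES
#'
#' A SMILES is valid when it tokenizes, its branches and ring bonds are
#' balanced, and the chemistry backend parses it into a molecule. Vectorized;
#' never throws on bad input.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
isValidSmiles <- function(smiles) {
  n <- length(smiles)
  ok <- logical(n)
  pre <- vapply(seq_len(n), function(i) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) return(FALSE)
    toks <- tryCatch(tokenizeSmiles(s), error = function(e) NULL)
    !is.null(toks) && .syntaxOk(toks)
  }, logical(1))
  if (any(pre)) {
    can <- .canonicalizeBatch(smiles[pre])
    ok[pre] <- !is.na(can)
  }
  ok
}

#' Canonicalize SMILES
#'
#' Vectorized canonicalization through the chemistry backend; NA where the
#' input does not parse.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES (NA on failure).
#' @export
canonicalSmiles <- function(smiles) {
  n <- length(smiles)
  res <- rep(NA_character_, n)
  pre <- vapply(seq_len(n), function(i) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) return(FALSE)
    toks <- tryCatch(tokenizeSmiles(s), error = function(e) NULL)
    !is.null(toks) && .syntaxOk(toks)
  }, logical(1))
  if (any(pre)) res[pre] <- .canonicalizeBatch(smiles[pre])
  res
}
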