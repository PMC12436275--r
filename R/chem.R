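# Molecular featurization: 2048-bit folded ECFP6 + 19 physicochemical
# descriptors = 2067-dimensional vectors, plus the min-max scaler.
#
# Fingerprints come from OpenBabel's ECFP6 implementation (4096 bits, folded
# by OR to 2048); bulk properties from OpenBabel descriptors; counts from
# SMARTS matching; ring-system descriptors from ring perception on the
# connection table.

.DESCRIPTOR_NAMES <- c(
  "mol_weight", "logp", "hba", "hbd", "rotatable_bonds", "amide_bonds",
  "bridgehead_atoms", "heteroatoms", "spiro_atoms", "heavy_atoms",
  "frac_csp3", "aliphatic_rings", "saturated_rings", "total_rings",
  "aromatic_rings", "heterocycles", "valence_electrons", "tpsa",
  "molar_refractivity")

#' Names of the feature-vector columns
#'
#' 2048 fingerprint bits (`fp0001`..`fp2048`) followed by the 19 descriptors.
#' @return character vector of length 2067.
#' @export
featureNames <- function() {
  c(sprintf("fp%04d", seq_len(2048L)), .DESCRIPTOR_NAMES)
}

# 4096-bit ECFP6 via the obabel CLI in one batch call, folded to 2048 bits.
.ecfp6 <- function(smiles) {
  n <- length(smiles)
  f <- tempfile(fileext = ".smi")
  on.exit(unlink(f))
  writeLines(paste0(smiles, " mfid", seq_len(n)), f)
  out <- suppressWarnings(
    system2("obabel", c(shQuote(f), "-ofps", "-xfECFP6"),
            stdout = TRUE, stderr = FALSE))
  lines <- out[!startsWith(out, "#")]
  bits <- matrix(0L, n, 4096L)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, function(p) p[length(p)], character(1))
    hex <- vapply(parts, `[[`, character(1), 1L)
    keep <- grepl("^mfid[0-9]+$", ids) & nchar(hex) == 1024L
    idx <- as.integer(sub("^mfid", "", ids[keep]))
    if (length(idx)) {
      nib <- t(vapply(strsplit(hex[keep], ""), function(h) strtoi(h, 16L),
                      integer(1024L)))
      bm <- matrix(0L, length(idx), 4096L)
      for (b in 1:4)
        bm[, seq(b, 4096L, by = 4L)] <- bitwAnd(bitwShiftR(nib, 4L - b), 1L)
      bits[idx, ] <- bm
    }
  }
  # fold 4096 -> 2048 by OR of the two halves
  fold <- bits[, 1:2048, drop = FALSE] | bits[, 2049:4096, drop = FALSE]
  storage.mode(fold) <- "integer"
  fold
}

.parseFormula <- function(formula) {
  formula <- gsub("[+-]+[0-9]*$", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Za-z]+", "", toks)
  ct <- ifelse(nzchar(ct), as.integer(ct), 1L)
  stats::setNames(ct, el)
}

# Ring-system descriptors for one molecule from its SDF connection table.
.ringDescriptors <- function(sdfMol) {
  ab <- ChemmineR::atomblock(sdfMol)
  bb <- ChemmineR::bondblock(sdfMol)
  nAtoms <- nrow(ab)
  nBonds <- if (is.null(dim(bb))) 0L else nrow(bb)
  # cyclomatic number of a connected molecule = size of the smallest ring basis
  totalRings <- max(0L, nBonds - nAtoms + 1L)
  res <- c(bridgehead_atoms = 0, spiro_atoms = 0, aliphatic_rings = 0,
           saturated_rings = 0, total_rings = totalRings,
           aromatic_rings = 0, heterocycles = 0)
  if (totalRings == 0L) return(res)
  ri <- tryCatch(ChemmineR::rings(sdfMol, upper = 7, type = "all",
                                  arom = TRUE),
                 error = function(e) NULL)
  if (is.null(ri) || !length(ri$RINGS)) return(res)
  ringAtoms <- lapply(ri$RINGS, function(r) as.integer(sub(".*_", "", r)))
  arom <- as.logical(ri$AROMATIC)
  elements <- sub("_.*", "", rownames(ab))
  bondOrder <- new.env(hash = TRUE)
  if (nBonds > 0L) {
    for (k in seq_len(nBonds)) {
      a <- bb[k, 1]; b <- bb[k, 2]
      assign(paste(min(a, b), max(a, b)), bb[k, 3], envir = bondOrder)
    }
  }
  ringBondOrders <- function(at) {
    m <- length(at)
    vapply(seq_len(m), function(j) {
      a <- at[j]; b <- at[if (j == m) 1L else j + 1L]
      get0(paste(min(a, b), max(a, b)), envir = bondOrder, ifnotfound = NA_real_)
    }, numeric(1))
  }
  res["aromatic_rings"] <- sum(arom)
  res["aliphatic_rings"] <- sum(!arom)
  res["heterocycles"] <- sum(vapply(ringAtoms, function(at)
    any(elements[at] != "C"), logical(1)))
  res["saturated_rings"] <- sum(vapply(seq_along(ringAtoms), function(i) {
    if (arom[i]) return(FALSE)
    ord <- ringBondOrders(ringAtoms[[i]])
    all(!is.na(ord) & ord == 1)
  }, logical(1)))
  # spiro: single shared atom between two rings; bridgehead: atoms interior
  # to a shared path of >= 3 atoms that carry three ring bonds
  nr <- length(ringAtoms)
  spiro <- integer(0); bridge <- integer(0)
  if (nr >= 2L) {
    adj <- vector("list", nAtoms)
    if (nBonds > 0L)
      for (k in seq_len(nBonds)) {
        a <- bb[k, 1]; b <- bb[k, 2]
        adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      }
    allRingAtoms <- unique(unlist(ringAtoms))
    for (i in seq_len(nr - 1L)) for (j in (i + 1L):nr) {
      shared <- intersect(ringAtoms[[i]], ringAtoms[[j]])
      if (length(shared) == 1L) {
        spiro <- union(spiro, shared)
      } else if (length(shared) >= 3L) {
        un <- union(ringAtoms[[i]], ringAtoms[[j]])
        deg <- vapply(shared, function(a)
          sum(adj[[a]] %in% un), numeric(1))
        bridge <- union(bridge, shared[deg >= 3])
      }
    }
  }
  res["spiro_atoms"] <- length(spiro)
  res["bridgehead_atoms"] <- length(bridge)
  res
}

#' Featurize molecules into 2067-dimensional vectors
#'
#' Computes, per molecule, the 2048-bit folded ECFP6 circular fingerprint
#' (radius 3) followed by 19 physicochemical descriptors in fixed order:
#' molecular weight, logP, H-bond acceptors, H-bond donors, rotatable bonds,
#' amide bonds, bridgehead atoms, heteroatoms, spiro atoms, heavy atoms,
#' fraction of sp3 carbons, aliphatic rings, saturated rings, total rings,
#' aromatic rings, heterocycles, valence electrons, topological polar surface
#' area and molar refractivity. Input SMILES are canonicalized first, so the
#' features (and any downstream prediction) are invariant to the SMILES
#' rendering.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric matrix `length(smiles)` x 2067, columns [featureNames()].
#' @export
featurize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  can <- canonicalSmiles(smiles)
  if (anyNA(can))
    stop(sprintf("invalid SMILES: '%s'", smiles[which(is.na(can))[1]]))
  n <- length(can)
  fp <- .ecfp6(can)

  ids <- paste0("mfid", seq_len(n))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(can, ids)))
  ChemmineR::cid(sdf) <- ids
  if (length(sdf) != n) stop("chemistry backend failed to parse a molecule")
  pr <- ChemmineR::propOB(sdf)

  countSmarts <- function(pattern)
    as.numeric(ChemmineR::smartsSearchOB(sdf, pattern, uniqueMatches = TRUE))
  rot <- countSmarts("[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  amide <- countSmarts("[CX3](=[OX1])[NX3]")
  hetero <- countSmarts("[!#6;!#1]")
  csp3 <- countSmarts("[CX4]")
  ctot <- countSmarts("[#6]")

  desc <- matrix(0, n, length(.DESCRIPTOR_NAMES),
                 dimnames = list(NULL, .DESCRIPTOR_NAMES))
  desc[, "mol_weight"] <- pr$MW
  desc[, "logp"] <- pr$logP
  desc[, "hba"] <- pr$HBA1
  desc[, "hbd"] <- pr$HBD
  desc[, "tpsa"] <- pr$TPSA
  desc[, "molar_refractivity"] <- pr$MR
  desc[, "rotatable_bonds"] <- rot
  desc[, "amide_bonds"] <- amide
  desc[, "heteroatoms"] <- hetero
  desc[, "frac_csp3"] <- ifelse(ctot > 0, csp3 / ctot, 0)
  for (i in seq_len(n)) {
    rd <- .ringDescriptors(sdf[[i]])
    desc[i, names(rd)] <- rd
    toks <- tokenizeSmiles(can[i])
    desc[i, "heavy_atoms"] <- .heavyAtomCount(toks)
    counts <- .parseFormula(pr$formula[i])
    ve <- .VALENCE_ELECTRONS[names(counts)]
    ve[is.na(ve)] <- 4  # unknown element fallback, never hit after filtering
    desc[i, "valence_electrons"] <- sum(ve * counts)
  }
  out <- cbind(fp, desc)
  colnames(out) <- featureNames()
  out
}

#' Min-max feature scaling
#'
#' `fitScaler` records per-feature minima and maxima on a training matrix;
#' `applyScaler` maps features affinely onto [0,1], sending features that
#' were constant in the fit set to 0 and clamping new out-of-range values.
#'
#' @param x numeric feature matrix (rows = molecules).
#' @param scaler a fitted scaler from `fitScaler`.
#' @return `fitScaler` a list with `lo` and `hi`; `applyScaler` the scaled
#'   matrix with all entries in [0,1].
#' @export
fitScaler <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  list(lo = apply(x, 2L, min), hi = apply(x, 2L, max))
}

#' @rdname fitScaler
#' @export
applyScaler <- function(x, scaler) {
  if (is.null(scaler$lo) || is.null(scaler$hi))
    stop("scaler has not been fitted")
  stopifnot(is.matrix(x), ncol(x) == length(scaler$lo))
  rng <- scaler$hi - scaler$lo
  out <- sweep(x, 2L, scaler$lo, "-")
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
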