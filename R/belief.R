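## Belief-function core: frames of discernment, BBAs, Bel/Pl, the
## conjunctive rule, Dempster's rule, n-source PCR6 and the pignistic
## transform.  Subsets are encoded as bitmasks over the frame's element
## order; at the user surface a subset is a character vector of labels or a
## single "|"-joined string ("T1|T3").

#' Construct a frame of discernment
#'
#' @param elements character vector of at least two distinct labels; the
#'   order is fixed and used for the canonical subset encoding.
#' @return a [FrameOfDiscernment-class].
#' @examples
#' frameOfDiscernment(c("T1", "T2", "T3"))
#' @export
frameOfDiscernment <- function(elements) {
  new("FrameOfDiscernment", elements = as.character(elements))
}

#' @describeIn frameElements Elements of a frame, in canonical order.
#' @param x a [FrameOfDiscernment-class] or [BBA-class].
#' @export
setMethod("frameElements", "FrameOfDiscernment", function(x) x@elements)

#' @describeIn frameElements Frame elements underlying a BBA.
#' @export
setMethod("frameElements", "BBA", function(x) x@fod@elements)

#' @name frameElements
#' @title Frame accessors
NULL

setMethod("show", "FrameOfDiscernment", function(object) {
  cat("FrameOfDiscernment with", length(object@elements), "elements:",
      paste(object@elements, collapse = ", "), "\n")
})

## ---- subset encoding -------------------------------------------------------

.subset_to_mask <- function(fod, subset) {
  if (is.numeric(subset) && length(subset) == 1 && subset == floor(subset))
    return(as.integer(subset))
  if (is.character(subset) && length(subset) == 1 && grepl("|", subset, fixed = TRUE))
    subset <- strsplit(subset, "|", fixed = TRUE)[[1]]
  idx <- match(subset, fod@elements)
  if (anyNA(idx))
    stop("labels not in the frame of discernment: ",
         paste(subset[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx)) stop("duplicate labels in subset")
  sum(bitwShiftL(1L, idx - 1L))
}

.mask_to_labels <- function(fod, mask) {
  fod@elements[bitwAnd(bitwShiftR(mask, seq_along(fod@elements) - 1L), 1L) == 1L]
}

.mask_key <- function(fod, mask) {
  if (mask == 0L) "{}" else paste(.mask_to_labels(fod, mask), collapse = "|")
}

.popcount <- function(mask) {
  n <- 0L
  while (mask > 0L) {
    n <- n + bitwAnd(mask, 1L)
    mask <- bitwShiftR(mask, 1L)
  }
  n
}

## ---- construction ----------------------------------------------------------

#' Construct a basic belief assignment
#'
#' Masses are stored exactly as given; no renormalization is performed, so a
#' mass vector that does not sum to 1 (tolerance 1e-9), a negative mass, an
#' empty-set key, or a key outside the frame raises a validation error.
#'
#' @param fod a [FrameOfDiscernment-class].
#' @param masses named numeric vector (or named list); each name is a
#'   "|"-joined subset of the frame, e.g. `c("T1" = 0.6, "T1|T2" = 0.4)`.
#' @return a validated [BBA-class].
#' @examples
#' fod <- frameOfDiscernment(c("T1", "T2", "T3"))
#' makeBBA(fod, c(T1 = 0.3, T2 = 0.3, T3 = 0.4))
#' @export
makeBBA <- function(fod, masses) {
  masses <- unlist(masses)
  if (is.null(names(masses)) || any(!nzchar(names(masses))))
    stop("every mass must be named by a '|'-joined subset key")
  sub <- vapply(names(masses), function(k) .subset_to_mask(fod, k), integer(1))
  if (any(sub == 0L)) stop("the empty set cannot be assigned mass")
  new("BBA", fod = fod, subsets = unname(sub),
      masses = unname(as.numeric(masses)))
}

#' The vacuous BBA (all mass on the full frame)
#'
#' @param fod a [FrameOfDiscernment-class].
#' @return the vacuous [BBA-class], the neutral element of Dempster's rule.
#' @export
vacuousBBA <- function(fod) {
  full <- bitwShiftL(1L, length(fod@elements)) - 1L
  new("BBA", fod = fod, subsets = full, masses = 1)
}

.bba_from_masks <- function(fod, subsets, masses, class = "BBA",
                            drop_zero = TRUE) {
  keep <- if (drop_zero) masses > 0 else rep(TRUE, length(masses))
  if (!any(keep)) { subsets <- integer(0); masses <- numeric(0) }
  else { subsets <- subsets[keep]; masses <- masses[keep] }
  o <- order(subsets)
  new(class, fod = fod, subsets = as.integer(unname(subsets[o])),
      masses = as.numeric(unname(masses[o])))
}

## ---- accessors -------------------------------------------------------------

#' @describeIn focalElements Focal elements of a BBA as a list of label
#'   vectors (subsets with strictly positive mass).
#' @param x a [BBA-class] or [UnnormalizedBBA-class].
#' @export
setMethod("focalElements", "BBA", function(x) {
  lapply(x@subsets[x@masses > 0], function(m) .mask_to_labels(x@fod, m))
})

#' @name focalElements
#' @title Focal elements
NULL

#' @describeIn massValues Named mass vector of a BBA ("|"-joined subset keys).
#' @param x a [BBA-class] or [UnnormalizedBBA-class].
#' @export
setMethod("massValues", "BBA", function(x) {
  stats::setNames(x@masses,
                  vapply(x@subsets, function(m) .mask_key(x@fod, m), ""))
})

#' @describeIn massValues Mass vector including any empty-set (conflict) mass,
#'   keyed `"{}"`.
#' @export
setMethod("massValues", "UnnormalizedBBA", function(x) {
  stats::setNames(x@masses,
                  vapply(x@subsets, function(m) .mask_key(x@fod, m), ""))
})

#' @name massValues
#' @title Mass vector accessor
NULL

#' Mass of one subset
#'
#' @param bba a [BBA-class] or [UnnormalizedBBA-class].
#' @param A subset as labels or "|"-joined key; `"{}"` for the empty set of
#'   an unnormalized BBA.
#' @return the stored mass (0 if A is not a focal element).
#' @export
massOf <- function(bba, A) {
  mask <- if (identical(A, "{}")) 0L else .subset_to_mask(bba@fod, A)
  i <- match(mask, bba@subsets)
  if (is.na(i)) 0 else unname(bba@masses[i])
}

#' @describeIn isBayesian TRUE when all focal elements are singletons.
#' @param x a [BBA-class].
#' @export
setMethod("isBayesian", "BBA", function(x) {
  foc <- x@subsets[x@masses > 0]
  all(vapply(foc, .popcount, integer(1)) == 1L)
})

#' @name isBayesian
#' @title Bayesian-BBA predicate
NULL

setMethod("show", "BBA", function(object) {
  cat("BBA over {", paste(object@fod@elements, collapse = ", "), "} — ",
      if (isBayesian(object)) "Bayesian" else "non-Bayesian", "\n", sep = "")
  m <- massValues(object)
  for (k in names(m)) cat(sprintf("  m(%s) = %.6f\n", k, m[[k]]))
})

setMethod("show", "UnnormalizedBBA", function(object) {
  cat("Unnormalized BBA over {", paste(object@fod@elements, collapse = ", "),
      "}\n", sep = "")
  m <- massValues(object)
  for (k in names(m)) cat(sprintf("  m(%s) = %.6f\n", k, m[[k]]))
})

## ---- belief and plausibility ----------------------------------------------

#' Belief and plausibility
#'
#' `belief(bba, A)` is the total mass of subsets of A; `plausibility(bba, A)`
#' is the total mass of subsets intersecting A.  `Pl(A) >= Bel(A)` always,
#' with equality on Bayesian BBAs at singletons.
#'
#' @param bba a [BBA-class].
#' @param A a subset of the frame, as labels or a "|"-joined key.
#' @return a value in [0, 1].
#' @name belief
#' @export
setMethod("belief", "BBA", function(bba, A) {
  a <- .subset_to_mask(bba@fod, A)
  sum(bba@masses[bitwAnd(bba@subsets, a) == bba@subsets])
})

#' @rdname belief
#' @export
setMethod("plausibility", "BBA", function(bba, A) {
  a <- .subset_to_mask(bba@fod, A)
  if (a == 0L) stop("plausibility of the empty set is not defined")
  sum(bba@masses[bitwAnd(bba@subsets, a) != 0L])
})

## ---- combination rules -----------------------------------------------------

.check_same_fod <- function(...) {
  bbas <- list(...)
  els <- lapply(bbas, function(b) b@fod@elements)
  if (!all(vapply(els[-1], identical, logical(1), els[[1]])))
    stop("BBAs must share the same frame of discernment")
}

#' Conjunctive combination (unnormalized)
#'
#' The mass of each subset A is the total product mass of focal-element
#' pairs whose intersection is A, including the empty set: the empty-set
#' entry is the conflict K.
#'
#' @param m1,m2 [BBA-class] objects on the same frame.
#' @return an [UnnormalizedBBA-class]; masses (including the conflict) sum
#'   to 1.
#' @export
combineConjunctive <- function(m1, m2) {
  .check_same_fod(m1, m2)
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(m1@subsets)) {
    for (j in seq_along(m2@subsets)) {
      inter <- bitwAnd(m1@subsets[i], m2@subsets[j])
      k <- as.character(inter)
      prev <- if (is.null(acc[[k]])) 0 else acc[[k]]
      acc[[k]] <- prev + m1@masses[i] * m2@masses[j]
    }
  }
  keys <- ls(acc)
  .bba_from_masks(m1@fod, as.integer(keys),
                  vapply(keys, function(k) acc[[k]], 0),
                  class = "UnnormalizedBBA", drop_zero = FALSE)
}

#' Conflict mass of an unnormalized BBA
#'
#' @param x an [UnnormalizedBBA-class].
#' @return the empty-set mass K.
#' @export
conflictMass <- function(x) {
  i <- match(0L, x@subsets)
  if (is.na(i)) 0 else x@masses[i]
}

#' Dempster's combination rule
#'
#' Conjunctive combination renormalized by 1/(1-K) with the empty-set
#' (conflict) mass removed.  Commutative, associative, with the vacuous BBA
#' as neutral element.
#'
#' @param m1,m2 [BBA-class] objects on the same frame.
#' @return the combined [BBA-class].
#' @examples
#' fod <- frameOfDiscernment(c("a", "b"))
#' m1 <- makeBBA(fod, c(a = 0.6, b = 0.4))
#' m2 <- makeBBA(fod, c(a = 0.7, b = 0.3))
#' massValues(combineDempster(m1, m2))  # a: 0.42/0.54, b: 0.12/0.54
#' @export
combineDempster <- function(m1, m2) {
  conj <- combineConjunctive(m1, m2)
  K <- conflictMass(conj)
  if (K > 1 - 1e-12)
    stop("total conflict (K = 1): Dempster's rule is undefined; consider PCR6")
  keep <- conj@subsets != 0L
  .bba_from_masks(m1@fod, conj@subsets[keep], conj@masses[keep] / (1 - K))
}

#' PCR6 combination (proportional conflict redistribution)
#'
#' For two sources this is the classical PCR6 formula: the conjunctive mass
#' plus, for every fully conflicting product, a redistribution to each
#' contributor proportional to its own mass.  For n > 2 sources the general
#' n-source PCR6 is applied by default: every n-tuple of focal elements with
#' empty joint intersection redistributes its product mass to each
#' contributing focal element in proportion to that source's mass.  PCR6 is
#' total (never fails on conflict) and commutative but not associative; a
#' sequential pairwise application is available for comparison.
#'
#' @param sources list of two or more [BBA-class] objects on a shared frame.
#' @param sequential if TRUE, fold the sources pairwise (left to right)
#'   instead of the joint n-source redistribution.
#' @return the combined [BBA-class].
#' @examples
#' fod <- frameOfDiscernment(c("a", "b"))
#' m1 <- makeBBA(fod, c(a = 0.6, b = 0.4))
#' m2 <- makeBBA(fod, c(a = 0.7, b = 0.3))
#' massValues(combinePCR6(list(m1, m2)))  # a ~ 0.71818, b ~ 0.28182
#' @export
combinePCR6 <- function(sources, sequential = FALSE) {
  if (!is.list(sources) || length(sources) < 2)
    stop("combinePCR6 needs a list of at least two BBAs")
  do.call(.check_same_fod, sources)
  if (sequential && length(sources) > 2) {
    out <- sources[[1]]
    for (k in 2:length(sources)) out <- combinePCR6(list(out, sources[[k]]))
    return(out)
  }
  fod <- sources[[1]]@fod
  n <- length(sources)
  subs <- lapply(sources, function(b) b@subsets[b@masses > 0])
  mas <- lapply(sources, function(b) b@masses[b@masses > 0])
  acc <- new.env(parent = emptyenv())
  add <- function(mask, x) {
    k <- as.character(mask)
    prev <- if (is.null(acc[[k]])) 0 else acc[[k]]
    acc[[k]] <- prev + x
  }
  idx <- rep(1L, n)
  lens <- vapply(subs, length, integer(1))
  repeat {
    masks <- vapply(seq_len(n), function(s) subs[[s]][idx[s]], integer(1))
    ms <- vapply(seq_len(n), function(s) mas[[s]][idx[s]], 0)
    p <- prod(ms)
    inter <- Reduce(bitwAnd, masks)
    if (inter != 0L) {
      add(inter, p)
    } else {
      denom <- sum(ms)
      for (s in seq_len(n)) add(masks[s], p * ms[s] / denom)
    }
    # next tuple
    s <- 1L
    while (s <= n) {
      idx[s] <- idx[s] + 1L
      if (idx[s] <= lens[s]) break
      idx[s] <- 1L
      s <- s + 1L
    }
    if (s > n) break
  }
  keys <- ls(acc)
  .bba_from_masks(fod, as.integer(keys), vapply(keys, function(k) acc[[k]], 0))
}

## ---- pignistic transform ---------------------------------------------------

#' Pignistic probability transform
#'
#' BetP(theta_i) = sum over focal elements A containing theta_i of
#' m(A)/|A|.  Bayesian BBAs are fixed points; the vacuous BBA maps to the
#' uniform distribution.
#'
#' @param bba a [BBA-class].
#' @return named probability vector over the frame elements (sums to 1).
#' @name pignistic
#' @export
setMethod("pignistic", "BBA", function(bba) {
  els <- bba@fod@elements
  out <- numeric(length(els))
  for (i in seq_along(bba@subsets)) {
    mask <- bba@subsets[i]
    card <- .popcount(mask)
    if (card == 0L) next
    member <- bitwAnd(bitwShiftR(mask, seq_along(els) - 1L), 1L) == 1L
    out[member] <- out[member] + bba@masses[i] / card
  }
  stats::setNames(out, els)
})

## ---- serialization ---------------------------------------------------------

#' Serialize / deserialize a BBA to the plain JSON mapping
#'
#' Format: `{"fod": [...], "masses": {"T1": x, "T1|T2": y, ...}}`.
#'
#' @param bba a [BBA-class].
#' @param path file path; for `bbaToJSON` omit to get the JSON string.
#' @return `bbaFromJSON` returns the [BBA-class]; `bbaToJSON` (invisibly)
#'   the JSON string.
#' @export
bbaToJSON <- function(bba, path = NULL) {
  x <- list(fod = bba@fod@elements, masses = as.list(massValues(bba)))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname bbaToJSON
#' @param json a JSON string (alternative to `path`).
#' @export
bbaFromJSON <- function(path = NULL, json = NULL) {
  x <- jsonlite::fromJSON(if (is.null(json)) path else json,
                          simplifyVector = FALSE)
  fod <- frameOfDiscernment(unlist(x$fod))
  makeBBA(fod, unlist(x$masses))
}
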