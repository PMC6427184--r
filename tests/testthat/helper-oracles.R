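# Brute-force belief-combination oracles on an independent representation:
# subsets are sorted character vectors, combination enumerates every tuple
# of focal elements explicitly.  Deliberately naive - these check the
# package's bitmask implementation, so they share no code with it.

# a mass table is a list of list(set = character vector, mass = numeric)
bba_to_table <- function(bba) {
  m <- massValues(bba)
  lapply(names(m), function(k) {
    set <- if (k == "{}") character(0) else
      sort(strsplit(k, "|", fixed = TRUE)[[1]])
    list(set = set, mass = unname(m[[k]]))
  })
}

table_lookup <- function(tab, set) {
  set <- sort(set)
  for (e in tab) if (identical(e$set, set)) return(e$mass)
  0
}

table_add <- function(tab, set, mass) {
  set <- sort(set)
  for (i in seq_along(tab)) {
    if (identical(tab[[i]]$set, set)) {
      tab[[i]]$mass <- tab[[i]]$mass + mass
      return(tab)
    }
  }
  c(tab, list(list(set = set, mass = mass)))
}

oracle_conjunctive <- function(t1, t2) {
  out <- list()
  for (a in t1) for (b in t2) {
    inter <- intersect(a$set, b$set)
    out <- table_add(out, inter, a$mass * b$mass)
  }
  out
}

oracle_dempster <- function(t1, t2) {
  conj <- oracle_conjunctive(t1, t2)
  K <- table_lookup(conj, character(0))
  out <- list()
  for (e in conj)
    if (length(e$set) > 0) out <- table_add(out, e$set, e$mass / (1 - K))
  out
}

# general n-source PCR6: conjunctive part plus, for every fully conflicting
# tuple, redistribution to each contributing focal element proportional to
# that source's mass
oracle_pcr6 <- function(tables) {
  idx <- do.call(expand.grid, lapply(tables, function(t) seq_along(t)))
  out <- list()
  for (r in seq_len(nrow(idx))) {
    els <- lapply(seq_along(tables), function(s) tables[[s]][[idx[r, s]]])
    inter <- Reduce(intersect, lapply(els, `[[`, "set"))
    p <- prod(vapply(els, `[[`, 0, "mass"))
    if (length(inter) > 0) {
      out <- table_add(out, inter, p)
    } else {
      denom <- sum(vapply(els, `[[`, 0, "mass"))
      for (e in els) out <- table_add(out, e$set, p * e$mass / denom)
    }
  }
  out
}

# compare a package BBA with an oracle table entrywise
expect_bba_matches_table <- function(bba, tab, tol = 1e-10) {
  sets <- unique(c(lapply(tab, `[[`, "set"),
                   lapply(bba_to_table(bba), `[[`, "set")))
  for (s in sets) {
    expect_equal(massOf(bba, if (length(s)) s else "{}"),
                 table_lookup(tab, s), tolerance = tol,
                 info = paste("subset", paste(s, collapse = "|")))
  }
}

# random BBA over a frame: random focal subsets with Dirichlet-ish masses
random_bba <- function(fod, bayesian = FALSE) {
  els <- frameElements(fod)
  subsets <- if (bayesian) as.list(els) else {
    all <- unlist(lapply(seq_along(els),
                         function(k) combn(els, k, simplify = FALSE)),
                  recursive = FALSE)
    all[sort(sample.int(length(all), sample(2:min(5, length(all)), 1)))]
  }
  w <- stats::rgamma(length(subsets), 1) + 1e-6
  w <- w / sum(w)
  names(w) <- vapply(subsets, paste, "", collapse = "|")
  makeBBA(fod, w)
}
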