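# Sequential binary partitions, orthonormal balances (ilr) and the
# Aitchison distance.

#' Sequential binary partition (SBP) balance scheme
#'
#' An SBP encodes D-1 orthonormal balances over D parts as a sign matrix:
#' each row splits one group of parts into a `+1` (numerator) and a `-1`
#' (denominator) subgroup, zeros marking parts not involved. The first row
#' must split the full part set and every later row must split a group left
#' intact by the earlier rows, so the rows form a balance dendrogram.
#'
#' @param signs Numeric matrix over `{-1, 0, 1}` with one column per part.
#'   Column names are taken as part labels unless `labels` is given.
#' @param labels Optional character vector of part labels.
#' @return An object of class `balance_scheme`: list with elements `labels`
#'   and `signs`.
#' @export
balance_scheme <- function(signs, labels = colnames(signs)) {
  signs <- as.matrix(signs)
  if (is.null(labels)) stop("part labels are required")
  if (length(labels) != ncol(signs) || anyDuplicated(labels)) {
    stop("labels must be unique, one per column")
  }
  if (!all(signs %in% c(-1, 0, 1))) {
    stop("sign matrix entries must be -1, 0 or +1")
  }
  for (k in seq_len(nrow(signs))) {
    if (!any(signs[k, ] == 1) || !any(signs[k, ] == -1)) {
      stop("row ", k, " must contain at least one +1 and one -1")
    }
  }
  validate_sbp_hierarchy(signs)
  colnames(signs) <- labels
  rownames(signs) <- paste0("b", seq_len(nrow(signs)))
  structure(list(labels = labels, signs = signs), class = "balance_scheme")
}

# Structural check: every row must split a group left whole by the others.
validate_sbp_hierarchy <- function(signs) {
  D <- ncol(signs)
  blocks <- list(seq_len(D))
  for (k in seq_len(nrow(signs))) {
    support <- which(signs[k, ] != 0)
    hit <- which(vapply(blocks, function(b) setequal(b, support), logical(1)))
    if (length(hit) == 0L) {
      stop("row ", k, " does not partition a group kept intact by the ",
           "other rows; not a valid sequential binary partition")
    }
    blocks[[hit[1]]] <- NULL
    blocks <- c(blocks,
                list(which(signs[k, ] == 1)),
                list(which(signs[k, ] == -1)))
  }
  invisible(TRUE)
}

#' @export
print.balance_scheme <- function(x, ...) {
  cat("balance scheme:", nrow(x$signs), "balances over",
      length(x$labels), "parts\n")
  print(x$signs, ...)
  invisible(x)
}

#' Orthonormal contrast matrix of a balance scheme
#'
#' Row k of the contrast matrix Psi carries `+sqrt(s / (r (r + s)))` at the
#' `+1` positions and `-sqrt(r / (s (r + s)))` at the `-1` positions, where
#' `r` and `s` count the `+1` and `-1` parts of that balance. Rows are
#' orthonormal (`Psi %*% t(Psi) = I`) and `ilr = Psi %*% clr`.
#'
#' @param scheme A [balance_scheme()].
#' @return Numeric matrix with one row per balance, columns named by part.
#' @export
contrast_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "balance_scheme"))
  signs <- scheme$signs
  psi <- matrix(0, nrow(signs), ncol(signs),
                dimnames = dimnames(signs))
  for (k in seq_len(nrow(signs))) {
    r <- sum(signs[k, ] == 1)
    s <- sum(signs[k, ] == -1)
    psi[k, signs[k, ] == 1] <- sqrt(s / (r * (r + s)))
    psi[k, signs[k, ] == -1] <- -sqrt(r / (s * (r + s)))
  }
  psi
}

#' Isometric log-ratio (ilr) coordinates of a composition
#'
#' Balance k takes the value `sqrt(r s / (r + s)) * ln(G_r / G_s)` with
#' `G_r`, `G_s` the geometric means over the numerator and denominator
#' parts. Numerically identical to `contrast_matrix(scheme) %*% clr`.
#'
#' @param x A [composition()].
#' @param scheme A [balance_scheme()] whose labels match `names(x)`.
#' @return Numeric vector of class `ilr` (one value per balance) with the
#'   scheme attached as attribute `scheme`.
#' @export
ilr_transform <- function(x, scheme) {
  stopifnot(inherits(x, "composition"), inherits(scheme, "balance_scheme"))
  if (!identical(names(x), scheme$labels)) {
    stop("composition labels do not match the balance scheme labels")
  }
  signs <- scheme$signs
  lx <- log(as.numeric(x))
  vals <- vapply(seq_len(nrow(signs)), function(k) {
    plus <- signs[k, ] == 1
    minus <- signs[k, ] == -1
    r <- sum(plus); s <- sum(minus)
    sqrt(r * s / (r + s)) * (mean(lx[plus]) - mean(lx[minus]))
  }, numeric(1))
  structure(stats::setNames(vals, rownames(signs)),
            scheme = scheme, class = "ilr")
}

#' @export
print.ilr <- function(x, ...) {
  cat("ilr coordinates (", length(x), " balances)\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Single balance between two part groups
#'
#' Convenience for one named contrast, e.g. the phloem-mobility balance of
#' mobile (N, P, K, Mg) against immobile (Ca, B) nutrients:
#' `sqrt(r s / (r + s)) * ln(G_plus / G_minus)`.
#'
#' @param x A [composition()].
#' @param plus,minus Disjoint character vectors of part labels.
#' @return The balance value (scalar).
#' @export
balance_value <- function(x, plus, minus) {
  stopifnot(inherits(x, "composition"))
  if (length(intersect(plus, minus)) > 0) stop("groups must be disjoint")
  miss <- setdiff(c(plus, minus), names(x))
  if (length(miss)) stop("unknown parts: ", paste(miss, collapse = ", "))
  lx <- stats::setNames(log(as.numeric(x)), names(x))
  r <- length(plus); s <- length(minus)
  sqrt(r * s / (r + s)) * (mean(lx[plus]) - mean(lx[minus]))
}

#' Aitchison (log-ratio Euclidean) distance between two compositions
#'
#' `sqrt(sum((clr_i - clr*_i)^2))`, identically equal to the Euclidean
#' distance between ilr coordinates under any valid balance scheme.
#'
#' @param a,b [composition()] objects with identical labels.
#' @param scheme Optional [balance_scheme()]; when supplied the distance is
#'   computed in ilr coordinates (same value, useful as a cross-check).
#' @return Nonnegative scalar.
#' @export
aitchison_distance <- function(a, b, scheme = NULL) {
  check_same_labels(a, b)
  if (is.null(scheme)) {
    sqrt(sum((as.numeric(clr_transform(a)) - as.numeric(clr_transform(b)))^2))
  } else {
    sqrt(sum((as.numeric(ilr_transform(a, scheme)) -
                as.numeric(ilr_transform(b, scheme)))^2))
  }
}

#' Draw a random valid sequential binary partition
#'
#' Recursively splits the part set in two at random. Uses the current RNG
#' state; seed upstream for reproducibility. Intended for property tests and
#' distance-equivalence checks.
#'
#' @param labels Character vector of part labels (length >= 2).
#' @return A [balance_scheme()] with `length(labels) - 1` balances.
#' @export
random_sbp <- function(labels) {
  D <- length(labels)
  if (D < 2) stop("need at least 2 parts")
  rows <- list()
  split_block <- function(idx) {
    if (length(idx) < 2) return(invisible(NULL))
    repeat {
      side <- sample(c(1, -1), length(idx), replace = TRUE)
      if (any(side == 1) && any(side == -1)) break
    }
    row <- numeric(D)
    row[idx] <- side
    rows[[length(rows) + 1L]] <<- row
    split_block(idx[side == 1])
    split_block(idx[side == -1])
  }
  split_block(seq_len(D))
  balance_scheme(do.call(rbind, rows), labels = labels)
}

#' Read a balance scheme from a CSV sign matrix
#'
#' The file's header row gives the part labels; each subsequent row is one
#' balance of `+1`/`-1`/`0` entries.
#'
#' @param path Path to the CSV file.
#' @return A [balance_scheme()].
#' @export
read_sbp <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  balance_scheme(as.matrix(tab), labels = colnames(tab))
}

#' Write a balance scheme to CSV
#'
#' @param scheme A [balance_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbp <- function(scheme, path) {
  stopifnot(inherits(scheme, "balance_scheme"))
  utils::write.csv(as.data.frame(scheme$signs), path, row.names = FALSE)
  invisible(path)
}
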