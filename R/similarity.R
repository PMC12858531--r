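#' Lin semantic similarity of two ontology terms
#'
#' `2 * IC(MICA) / (IC(a) + IC(b))` where MICA is the common ancestor
#' (including the terms themselves) with maximal information content.
#' Conventions: identical annotated non-root terms score 1; a pair whose
#' only common ancestor is the root scores 0; a pair of roots
#' (`IC(a) + IC(b) = 0`) is defined as 0 to avoid 0/0; terms from
#' different namespaces score 0; terms with undefined IC raise an error
#' (matrix construction skips them instead).
#'
#' @param a,b Term IDs.
#' @param dag An `ontology_dag` with IC ([compute_ic()]).
#' @return Similarity in `[0, 1]`.
#' @export
lin_similarity <- function(a, b, dag) {
  if (is.null(dag$ic)) stop("run compute_ic() first", call. = FALSE)
  ic_a <- dag$ic[[a]]
  ic_b <- dag$ic[[b]]
  if (is.na(ic_a) || is.na(ic_b)) {
    stop("undefined IC for term(s): ",
         paste(c(a, b)[is.na(c(ic_a, ic_b))], collapse = ", "),
         call. = FALSE)
  }
  if (dag$namespace[[a]] != dag$namespace[[b]]) return(0)
  if (ic_a + ic_b == 0) return(0)
  common <- intersect(c(a, term_ancestors(a, dag)),
                      c(b, term_ancestors(b, dag)))
  if (length(common) == 0) return(0)
  ic_mica <- max(dag$ic[common], na.rm = TRUE)
  2 * ic_mica / (ic_a + ic_b)
}

#' Pairwise Lin similarity matrix
#'
#' Terms with undefined IC (no propagated annotations) are excluded from
#' the matrix; they are treated as dissimilar to everything downstream.
#'
#' @param terms Character vector of term IDs.
#' @param dag An `ontology_dag` with IC.
#' @return Symmetric numeric matrix with dimnames = retained terms;
#'   diagonal 1 for annotated non-root terms.
#' @export
lin_sim_matrix <- function(terms, dag) {
  terms <- unique(terms)
  terms <- terms[terms %in% dag$terms & !is.na(dag$ic[terms])]
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  diag(m) <- ifelse(dag$ic[terms] > 0, 1, 0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- lin_similarity(terms[i], terms[j], dag)
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  m
}

#' Tanimoto similarity of two sets
#'
#' Intersection over union of two chemical membership lists.
#'
#' @param c_i,c_j Character vectors (at least one non-empty).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(c_i, c_j) {
  c_i <- unique(c_i)
  c_j <- unique(c_j)
  u <- length(union(c_i, c_j))
  if (u == 0) stop("Tanimoto similarity of two empty sets is undefined",
                   call. = FALSE)
  length(intersect(c_i, c_j)) / u
}

#' Pairwise Tanimoto similarity matrix over a list of sets
#'
#' @param sets Named list of character vectors.
#' @return Symmetric numeric matrix.
#' @export
tanimoto_matrix <- function(sets) {
  n <- length(sets)
  m <- diag(1, nrow = n)
  dimnames(m) <- list(names(sets), names(sets))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- tanimoto(sets[[i]], sets[[j]])
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  m
}

#' Connected components of a thresholded similarity graph
#'
#' Items i and j (i != j) are connected iff `similarity >= threshold`
#' (">=" so the commonly printed thresholds 0.5/0.75/0.9 include exact
#' ties); components of the resulting undirected graph are returned,
#' singletons included. Raising the threshold never merges components.
#'
#' @param matrix Symmetric similarity matrix with dimnames.
#' @param threshold Numeric in `[0, 1]`.
#' @return List with `membership` (named integer vector) and
#'   `components` (list of character vectors).
#' @export
threshold_components <- function(matrix, threshold) {
  stopifnot(is.matrix(matrix), threshold >= 0, threshold <= 1,
            nrow(matrix) == ncol(matrix))
  adj <- (matrix >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  membership <- comp$membership
  names(membership) <- rownames(matrix)
  list(
    membership = membership,
    components = split(names(membership), membership)
  )
}
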