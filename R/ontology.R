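#' Read a GO-style ontology from OBO format
#'
#' Minimal OBO reader covering `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a` and `is_obsolete` tags; obsolete terms and
#' relationship types other than `is_a` are ignored. Cycles are rejected.
#'
#' @param path Path to an `.obo` file.
#' @return An object of class `ontology_dag`: list with `terms`
#'   (character), `name`, `namespace` (named character), and `parents`
#'   (named list child -> parent IDs).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur, out) {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete)) {
      out[[cur$id]] <- cur
    }
    out
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      out <- flush(cur, out)
      cur <- list(parents = character(0))
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      out <- flush(cur, out)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      key <- sub(":.*$", "", ln)
      val <- trimws(sub("^[^:]+:\\s*", "", ln))
      if (key == "id") cur$id <- val
      else if (key == "name") cur$name <- val
      else if (key == "namespace") cur$namespace <- val
      else if (key == "is_a") {
        cur$parents <- c(cur$parents, sub("\\s.*$", "", val))
      } else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    }
  }
  out <- flush(cur, out)
  ids <- names(out)
  dag <- list(
    terms = ids,
    name = vapply(out, function(t) t$name %||% NA_character_, character(1)),
    namespace = vapply(out, function(t) t$namespace %||% "default",
                       character(1)),
    parents = lapply(out, function(t) intersect(t$parents, ids))
  )
  class(dag) <- "ontology_dag"
  assert_acyclic(dag)
  dag
}

#' Build an ontology DAG from edge pairs
#'
#' Convenience constructor used by tests and the fixture generator.
#'
#' @param child,parent Equal-length character vectors of is_a edges.
#' @param namespace Optional named character vector term -> namespace.
#' @return An `ontology_dag`.
#' @export
ontology_from_edges <- function(child, parent, namespace = NULL) {
  ids <- sort(unique(c(child, parent)))
  parents <- lapply(stats::setNames(ids, ids), function(t)
    unique(parent[child == t]))
  ns <- stats::setNames(rep("default", length(ids)), ids)
  if (!is.null(namespace)) ns[names(namespace)] <- namespace
  dag <- list(terms = ids,
              name = stats::setNames(ids, ids),
              namespace = ns,
              parents = parents)
  class(dag) <- "ontology_dag"
  assert_acyclic(dag)
  dag
}

assert_acyclic <- function(dag) {
  # Kahn peeling: repeatedly drop terms with no remaining parents
  remaining <- dag$terms
  repeat {
    if (length(remaining) == 0) return(invisible(TRUE))
    drop <- remaining[vapply(dag$parents[remaining], function(p)
      length(intersect(p, remaining)) == 0, logical(1))]
    if (length(drop) == 0) {
      stop("ontology contains a cycle involving: ",
           paste(utils::head(remaining, 5), collapse = ", "),
           call. = FALSE)
    }
    remaining <- setdiff(remaining, drop)
  }
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("<ontology_dag> ", length(x$terms), " terms, ",
      sum(lengths(x$parents)), " is_a edges\n", sep = "")
  invisible(x)
}

#' All ancestors of a term (excluding itself)
#'
#' @param term Term ID.
#' @param dag An `ontology_dag`.
#' @return Character vector of ancestor IDs.
#' @export
term_ancestors <- function(term, dag) {
  seen <- character(0)
  frontier <- dag$parents[[term]] %||% character(0)
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
  }
  seen
}

#' Propagate annotation counts and compute information content
#'
#' Every annotation record increments its term and each of that term's
#' ancestors exactly once (ancestor-set union, so diamond paths do not
#' double-count); repeated annotations count separately. The information
#' content of a term is `-log(count(term) / count(root))` with the
#' natural logarithm, where the root is the term's namespace root
#' (a term with no parents). The root therefore has IC 0 and IC is
#' non-decreasing from root to descendants. Terms with zero propagated
#' count have undefined (NA) IC and are treated as dissimilar to
#' everything by [lin_similarity()].
#'
#' @param dag An `ontology_dag`.
#' @param annotations Tibble with a `go_id` column (one row per
#'   annotation record, e.g. a gene2go table). Annotations to unknown
#'   terms are reported via a message and skipped.
#' @return The `dag` with added fields `counts` (named numeric) and `ic`
#'   (named numeric, NA where undefined).
#' @export
compute_ic <- function(dag, annotations) {
  terms <- annotations$go_id
  unknown <- setdiff(unique(terms), dag$terms)
  if (length(unknown) > 0) {
    message("compute_ic: skipping ", sum(terms %in% unknown),
            " annotation(s) to ", length(unknown), " unknown term(s)")
    terms <- terms[!terms %in% unknown]
  }
  counts <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  anc_cache <- new.env(parent = emptyenv())
  for (t in terms) {
    anc <- get0(t, envir = anc_cache, ifnotfound = NULL)
    if (is.null(anc)) {
      anc <- c(t, term_ancestors(t, dag))
      assign(t, anc, envir = anc_cache)
    }
    counts[anc] <- counts[anc] + 1
  }
  # namespace root count: max count among parentless terms per namespace
  is_root <- lengths(dag$parents) == 0
  root_count <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  for (ns in unique(dag$namespace)) {
    in_ns <- dag$namespace == ns
    roots <- dag$terms[in_ns & is_root]
    root_count[dag$terms[in_ns]] <- max(counts[roots], 0)
  }
  ic <- ifelse(counts > 0 & root_count > 0, -log(counts / root_count),
               NA_real_)
  dag$counts <- counts
  dag$ic <- stats::setNames(as.numeric(ic), dag$terms)
  dag
}
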