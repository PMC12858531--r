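# Internal helpers for set-valued columns. CTD-dialect TSVs encode sets
# (PubMed IDs, anatomy terms, evidence labels) as pipe-delimited strings;
# tables keep the string form so SQLite round-trips are byte-exact, and
# these helpers convert at the point of use.

split_set <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  out <- strsplit(x, "|", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_set <- function(v) paste(sort(unique(v)), collapse = "|")

# union of pipe-delimited cells -> character vector
set_union <- function(x) {
  unique(unlist(split_set(x), use.names = FALSE))
}

# does each pipe-delimited cell intersect `ref`?
set_intersects <- function(x, ref) {
  vapply(split_set(x), function(v) any(v %in% ref), logical(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
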