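# Population-model files ----------------------------------------------------
#
# A population model names populations and assigns individuals to them,
# optionally with a population tree (newick-like string). Several models live
# together in a JSON model file so one document can drive a whole pipeline
# (e.g. a 2-population and a 4-population sampling design over the same
# cohort). The JSON dialect: a top-level list of model objects, each
#   {"name": str, "tree": str|null, "pops": {popName: {"inds": [str, ...]}}}
# Population order is the key order in the file. Unknown extra keys are kept
# and re-emitted on write.

#' Create a population model
#'
#' @param name Model name (non-empty string).
#' @param pops Named list: population name -> character vector of individual
#'   IDs. Order is preserved and meaningful (it fixes sample order in every
#'   downstream exporter).
#' @param tree Optional newick-like population tree string. Only balanced
#'   parentheses are checked; no phylogeny grammar is enforced.
#' @return A `pop_model` object.
#' @examples
#' m <- pop_model("chimps", list(CT = c("c1", "c2"), WC = c("w1", "w2")))
#' model_sizes(m)
#' @export
pop_model <- function(name, pops, tree = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    rlang::abort("model name must be a non-empty string")
  }
  if (length(pops) < 1) rlang::abort("a model needs at least one population")
  if (is.null(names(pops)) || any(!nzchar(names(pops)))) {
    rlang::abort("pops must be a named list of populations")
  }
  if (anyDuplicated(names(pops))) {
    rlang::abort("duplicate population name within model")
  }
  pops <- lapply(pops, as.character)
  if (any(lengths(pops) == 0)) rlang::abort("every population must be non-empty")
  inds <- unlist(pops, use.names = FALSE)
  if (anyDuplicated(inds)) {
    dup <- unique(inds[duplicated(inds)])
    rlang::abort(paste0(
      "individual(s) assigned to more than one population: ",
      paste(dup, collapse = ", ")
    ))
  }
  if (!is.null(tree)) {
    tree <- as.character(tree)
    n_open <- stringr::str_count(tree, stringr::fixed("("))
    n_close <- stringr::str_count(tree, stringr::fixed(")"))
    if (n_open != n_close) rlang::abort("tree string has unbalanced parentheses")
  }
  structure(list(name = name, tree = tree, pops = pops, extra = list()),
    class = "pop_model"
  )
}

#' @export
print.pop_model <- function(x, ...) {
  cat(sprintf(
    "Population model '%s': %d population(s), %d individual(s)\n",
    x$name, length(x$pops), length(model_individuals(x))
  ))
  for (p in names(x$pops)) {
    cat(sprintf("  %s: %s\n", p, paste(x$pops[[p]], collapse = ", ")))
  }
  if (!is.null(x$tree)) cat("  tree:", x$tree, "\n")
  invisible(x)
}

#' Individuals of a model, in model order
#'
#' The concatenation of each population's individuals, populations in model
#' order. This ordering contract is relied on by every exporter.
#'
#' @param model A `pop_model`.
#' @return Character vector of individual IDs.
#' @export
model_individuals <- function(model) {
  unlist(model$pops, use.names = FALSE)
}

#' Haploid sample sizes per population
#'
#' @param model A `pop_model`.
#' @param ploidy Copies per individual (default 2, diploid).
#' @return Named integer vector: population -> ploidy x individuals.
#' @export
model_sizes <- function(model, ploidy = 2) {
  if (ploidy < 1) rlang::abort("ploidy must be >= 1")
  vapply(model$pops, function(p) as.integer(ploidy * length(p)), integer(1))
}

#' Population membership lookup
#'
#' @param model A `pop_model`.
#' @return Named character vector mapping individual -> population.
#' @export
model_pop_of <- function(model) {
  stats::setNames(
    rep(names(model$pops), lengths(model$pops)),
    unlist(model$pops, use.names = FALSE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a population model
#'
#' @param x A `pop_model`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `pop`, `individual`.
#' @export
tidy.pop_model <- function(x, ...) {
  tibble::tibble(
    model = x$name,
    pop = rep(names(x$pops), lengths(x$pops)),
    individual = unlist(x$pops, use.names = FALSE)
  )
}

# Model files ---------------------------------------------------------------

#' Assemble models into a model file object
#'
#' A model file holds several named population models; an individual may
#' appear in more than one model (different sampling designs over one
#' cohort), but never in two populations of the same model.
#'
#' @param ... `pop_model` objects (or a single list of them).
#' @return A `model_file`: named list of models keyed by model name.
#' @export
model_file <- function(...) {
  models <- list(...)
  if (length(models) == 1 && !inherits(models[[1]], "pop_model")) {
    models <- models[[1]]
  }
  ok <- vapply(models, inherits, logical(1), "pop_model")
  if (length(models) == 0 || !all(ok)) {
    rlang::abort("model_file() takes one or more pop_model objects")
  }
  nm <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nm)) rlang::abort("duplicate model names in model file")
  structure(stats::setNames(models, nm), class = "model_file")
}

#' Read or write a JSON model file
#'
#' The on-disk dialect is a UTF-8 JSON array of model objects
#' `{"name": ..., "tree": ..., "pops": {pop: {"inds": [...]}}}`; population
#' order is key order. Extra keys on a model object survive a read/write
#' round trip untouched.
#'
#' @param path File path.
#' @return `read_model_file()` returns a `model_file`.
#' @export
read_model_file <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || length(raw) == 0) {
    rlang::abort("model file must contain a non-empty list of models")
  }
  models <- lapply(raw, function(m) {
    if (is.null(m$name) || is.null(m$pops)) {
      rlang::abort("model entry missing required 'name' or 'pops' key")
    }
    pops <- lapply(m$pops, function(p) unlist(p$inds, use.names = FALSE))
    mod <- pop_model(m$name, pops, tree = m$tree)
    mod$extra <- m[setdiff(names(m), c("name", "tree", "pops"))]
    mod
  })
  model_file(models)
}

#' @param models A `model_file` (or single `pop_model`).
#' @rdname read_model_file
#' @export
write_model_file <- function(models, path) {
  if (inherits(models, "pop_model")) models <- model_file(models)
  payload <- lapply(unname(models), function(m) {
    obj <- c(
      list(
        name = jsonlite::unbox(m$name),
        tree = if (is.null(m$tree)) NULL else jsonlite::unbox(m$tree),
        pops = lapply(m$pops, function(inds) list(inds = as.list(inds)))
      ),
      m$extra
    )
    obj
  })
  jsonlite::write_json(payload, path, null = "null", auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
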