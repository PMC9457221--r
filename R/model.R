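#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# Reserved symbol through which the feedback signal enters the rate equations.
FEEDBACK_SYMBOL <- "F"

## ---- expression grammar -----------------------------------------------------
## Rate and feedback expressions use a deliberately small grammar: identifiers,
## decimal / scientific literals, + - * / ^, unary minus, parentheses. No
## function calls, so Hill terms are written out, e.g. "mu_W/(1 + (Y/K)^n)".

ALLOWED_OPS <- c("+", "-", "*", "/", "^", "(")

parse_expr <- function(text, where = "expression") {
  stopifnot(is.character(text), length(text) == 1L)
  ex <- tryCatch(
    str2lang(text),
    error = function(e) {
      stop(sprintf("cannot parse %s: %s (in \"%s\")", where, conditionMessage(e), text),
           call. = FALSE)
    }
  )
  check_grammar(ex, where, text)
  ex
}

check_grammar <- function(ex, where, text) {
  if (is.numeric(ex) || is.symbol(ex)) return(invisible(TRUE))
  if (is.call(ex)) {
    op <- as.character(ex[[1L]])
    if (!op %in% ALLOWED_OPS) {
      stop(sprintf("disallowed operator or function \"%s\" in %s \"%s\"", op, where, text),
           call. = FALSE)
    }
    for (i in seq_along(ex)[-1L]) check_grammar(ex[[i]], where, text)
    return(invisible(TRUE))
  }
  stop(sprintf("unsupported token in %s \"%s\"", where, text), call. = FALSE)
}

expr_identifiers <- function(ex) {
  if (is.symbol(ex)) return(as.character(ex))
  if (is.call(ex)) {
    return(unique(unlist(lapply(as.list(ex)[-1L], expr_identifiers))))
  }
  character(0)
}

## ---- ModelSpec --------------------------------------------------------------

#' Define an ODE feedback model
#'
#' A model couples named species and parameters to one rate expression per
#' species, plus a designated feedback-signal expression and a designated
#' controlled (output) species. The reserved symbol `F` is the single channel
#' through which the feedback acts: in the intact system `F` is bound to
#' `feedback`, and the locally analogous no-feedback system is obtained by
#' freezing `F` to a constant (see [freeze_feedback()]).
#'
#' Expressions use a small arithmetic grammar: identifiers, numeric literals,
#' `+ - * / ^`, unary minus and parentheses; no function calls. Hill terms are
#' written explicitly, e.g. `"mu_W/(1 + (Y/K)^n)"`. Time is conventionally in
#' minutes; concentrations are unit-agnostic.
#'
#' @param name model name (used in printing and serialization).
#' @param species character vector of species identifiers; declaration order is
#'   the state-vector order.
#' @param parameters named numeric vector of strictly positive default values.
#' @param rates named list/character vector mapping each species to its rate
#'   expression (may reference species, parameters and `F`).
#' @param feedback expression string for the feedback signal f(Y).
#' @param output identifier of the controlled species Y.
#' @param f_const optional constant to which `F` is frozen; `NULL` (default)
#'   means the dynamic feedback expression is used.
#' @param quiet suppress the open-loop warning when `feedback` does not
#'   reference the output species (used by deliberately open-loop fixtures).
#'
#' @return An object of class `cora_model`.
#' @examples
#' m <- model_spec("decay", species = "Y",
#'                 parameters = c(mu = 1, gamma = 0.1),
#'                 rates = list(Y = "F - gamma*Y"),
#'                 feedback = "mu", output = "Y", quiet = TRUE)
#' evaluate_rates(m, c(Y = 0))
#' @seealso [parse_model()], [motifs], [freeze_feedback()]
#' @export
model_spec <- function(name, species, parameters, rates, feedback, output,
                       f_const = NULL, quiet = FALSE) {
  stopifnot(is.character(species), length(species) >= 1L, !anyDuplicated(species))
  parameters <- unlist(parameters)
  if (is.null(names(parameters)) || any(names(parameters) == "")) {
    stop("all parameters must be named", call. = FALSE)
  }
  if (any(!is.finite(parameters)) || any(parameters < 0)) {
    stop("all parameter defaults must be finite and nonnegative", call. = FALSE)
  }
  if (FEEDBACK_SYMBOL %in% c(species, names(parameters))) {
    stop(sprintf("\"%s\" is reserved for the feedback signal", FEEDBACK_SYMBOL), call. = FALSE)
  }
  if (!output %in% species) {
    stop(sprintf("output species \"%s\" is not a declared species", output), call. = FALSE)
  }
  rates <- lapply(rates, function(x) if (is.character(x)) x else stop("rates must be strings"))
  if (!setequal(names(rates), species)) {
    stop("rates must define exactly one expression per declared species", call. = FALSE)
  }
  rates <- rates[species]  # state-vector order = declaration order

  known <- c(species, names(parameters), FEEDBACK_SYMBOL)
  rate_exprs <- lapply(species, function(sp) {
    ex <- parse_expr(rates[[sp]], where = sprintf("rate of %s", sp))
    unknown <- setdiff(expr_identifiers(ex), known)
    if (length(unknown)) {
      stop(sprintf("rate of %s references undeclared identifier(s): %s",
                   sp, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    ex
  })
  names(rate_exprs) <- species

  fb_expr <- parse_expr(feedback, where = "feedback expression")
  unknown <- setdiff(expr_identifiers(fb_expr), c(species, names(parameters)))
  if (length(unknown)) {
    stop(sprintf("feedback expression references undeclared identifier(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  uses_f <- vapply(rate_exprs, function(ex) FEEDBACK_SYMBOL %in% expr_identifiers(ex), logical(1))
  if (!any(uses_f)) {
    stop(sprintf("the reserved symbol %s appears in no rate expression; there is no feedback channel to quantify",
                 FEEDBACK_SYMBOL), call. = FALSE)
  }
  if (!quiet && !output %in% expr_identifiers(fb_expr)) {
    warning(sprintf("feedback expression \"%s\" does not reference the output species %s; this model is effectively open-loop",
                    feedback, output), call. = FALSE)
  }

  structure(
    list(
      name = as.character(name),
      species = species,
      parameters = parameters,
      rate_strings = unlist(rates),
      rate_exprs = rate_exprs,
      feedback_string = feedback,
      feedback_expr = fb_expr,
      output = output,
      f_const = f_const
    ),
    class = if (is.null(f_const)) "cora_model" else c("cora_analog", "cora_model")
  )
}

#' @export
print.cora_model <- function(x, ...) {
  kind <- if (inherits(x, "cora_analog")) "no-feedback analogue" else "feedback model"
  cat(sprintf("<%s> %s\n", kind, x$name))
  cat("  species:   ", paste(x$species, collapse = ", "), "\n")
  cat("  output:    ", x$output, "\n")
  for (sp in x$species) cat(sprintf("  d%s/dt = %s\n", sp, x$rate_strings[[sp]]))
  if (inherits(x, "cora_analog")) {
    cat(sprintf("  F = %.9g (frozen; was %s)\n", x$f_const, x$feedback_string))
  } else {
    cat(sprintf("  F = %s\n", x$feedback_string))
  }
  pp <- paste(sprintf("%s=%.4g", names(x$parameters), x$parameters), collapse = ", ")
  cat("  parameters:", pp, "\n")
  invisible(x)
}

## ---- parameter handling -----------------------------------------------------

#' Resolve a parameter set against a model
#'
#' Takes the model's defaults and applies overrides; validates that every key
#' is a known parameter and every value strictly positive.
#'
#' @param model a `cora_model`.
#' @param theta `NULL` (defaults), or a named numeric vector/list of overrides,
#'   or a complete named parameter vector.
#' @return named numeric vector with one entry per model parameter.
#' @export
resolve_theta <- function(model, theta = NULL) {
  out <- model$parameters
  if (is.null(theta)) return(out)
  theta <- unlist(theta)
  if (is.null(names(theta)) || any(names(theta) == "")) {
    stop("theta overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(theta), names(out))
  if (length(unknown)) {
    stop(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop("parameter values must be finite and nonnegative", call. = FALSE)
  }
  out[names(theta)] <- theta
  out
}

## ---- rate evaluation --------------------------------------------------------

#' Evaluate a model's rate equations
#'
#' Computes d(state)/dt for a state vector, with the feedback symbol `F` either
#' bound dynamically to the model's feedback expression or to a supplied
#' constant. Evaluation is pure: identical arguments give identical results.
#'
#' @param model a `cora_model`.
#' @param state numeric state vector in species order (names optional).
#' @param theta parameter overrides (see [resolve_theta()]).
#' @param f_value `"dynamic"` to bind `F` to the feedback expression at the
#'   current state, or a single numeric constant, or `NULL` for the model's
#'   default binding (dynamic for a feedback model; for a frozen analogue, the
#'   feedback expression with species pinned at the reference steady state and
#'   parameters live).
#' @return numeric vector of derivatives, one per species in species order.
#' @export
evaluate_rates <- function(model, state, theta = NULL, f_value = NULL) {
  theta <- resolve_theta(model, theta)
  if (is.null(f_value)) f_value <- default_f_value(model, theta)
  ns <- length(model$species)
  if (length(state) != ns) {
    stop(sprintf("state has length %d but model has %d species", length(state), ns),
         call. = FALSE)
  }
  env <- rate_env(model, theta)
  eval_rates_env(model, as.numeric(state), env, f_value)
}

# Reusable evaluation environment holding the parameters; state and F are
# rebound on each call. Kept separate so solvers can amortize the setup.
rate_env <- function(model, theta) {
  env <- new.env(parent = baseenv())
  for (p in names(theta)) assign(p, theta[[p]], envir = env)
  env
}

eval_rates_env <- function(model, state, env, f_value) {
  sp <- model$species
  for (i in seq_along(sp)) assign(sp[[i]], state[[i]], envir = env)
  fv <- if (identical(f_value, "dynamic")) eval(model$feedback_expr, env) else as.numeric(f_value)
  assign(FEEDBACK_SYMBOL, fv, envir = env)
  out <- numeric(length(sp))
  for (i in seq_along(sp)) {
    v <- eval(model$rate_exprs[[i]], env)
    if (!is.finite(v)) {
      stop(sprintf("non-finite derivative for species %s (state: %s)",
                   sp[[i]], paste(signif(state, 6), collapse = ", ")), call. = FALSE)
    }
    out[[i]] <- v
  }
  names(out) <- sp
  out
}

# Default binding for the feedback symbol. A frozen analogue keeps the
# feedback expression's parameter dependence but pins its species dependence
# at the reference steady state: the constant input mimics the direct
# influence of Y (and only that influence), so a perturbation to a rate
# constant inside the feedback term still reaches the no-feedback system.
default_f_value <- function(model, theta) {
  if (is.null(model$f_const)) return("dynamic")
  if (!is.null(model$frozen_state)) return(eval_feedback(model, model$frozen_state, theta))
  model$f_const
}

# Evaluate the feedback expression at a state.
eval_feedback <- function(model, state, theta = NULL) {
  theta <- resolve_theta(model, theta)
  env <- rate_env(model, theta)
  sp <- model$species
  for (i in seq_along(sp)) assign(sp[[i]], as.numeric(state)[[i]], envir = env)
  eval(model$feedback_expr, env)
}

## ---- model documents --------------------------------------------------------

#' Read a model from a declarative JSON document
#'
#' The document mirrors [model_spec()]: keys `name`, `species` (array),
#' `parameters` (object of defaults), `rates` (object species -> expression),
#' `feedback` (expression string), `output` (species id). The built-in motifs
#' ship as documents under `system.file("extdata/models", package = "cora")`.
#'
#' @param source path to a JSON file, or a JSON string.
#' @param strict if `TRUE`, the open-loop warning (feedback expression not
#'   referencing the output) is promoted to an error.
#' @return a validated `cora_model`.
#' @examples
#' path <- system.file("extdata/models", "open_loop.json", package = "cora")
#' parse_model(path)
#' @export
parse_model <- function(source, strict = FALSE) {
  doc <- tryCatch(
    jsonlite::fromJSON(source, simplifyVector = TRUE),
    error = function(e) stop(sprintf("cannot read model document: %s", conditionMessage(e)),
                             call. = FALSE)
  )
  need <- c("name", "species", "parameters", "rates", "feedback", "output")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop(sprintf("model document is missing field(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  build <- function(quiet) {
    model_spec(
      name = doc$name,
      species = as.character(doc$species),
      parameters = unlist(doc$parameters),
      rates = as.list(unlist(doc$rates)),
      feedback = as.character(doc$feedback),
      output = as.character(doc$output),
      quiet = quiet
    )
  }
  if (strict) {
    withCallingHandlers(build(quiet = FALSE), warning = function(w) {
      stop(conditionMessage(w), call. = FALSE)
    })
  } else {
    build(quiet = TRUE) -> m
    # still warn (not in strict mode) so interactive users see it
    fb_ids <- expr_identifiers(m$feedback_expr)
    if (!m$output %in% fb_ids) {
      message(sprintf("note: feedback expression of \"%s\" does not reference output %s (open loop)",
                      m$name, m$output))
    }
    m
  }
}

#' Serialize a model to a JSON document
#'
#' Inverse of [parse_model()]; a frozen analogue serializes with its feedback
#' expression replaced by the frozen constant.
#'
#' @param model a `cora_model`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return invisibly the JSON string.
#' @export
write_model <- function(model, path = NULL) {
  fb <- if (inherits(model, "cora_analog")) format(model$f_const, digits = 17) else model$feedback_string
  doc <- list(
    name = model$name,
    species = model$species,
    parameters = as.list(model$parameters),
    rates = as.list(model$rate_strings),
    feedback = fb,
    output = model$output
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}
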