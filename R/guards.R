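#' Transition guard expressions
#'
#' State-machine transitions (and migration-rule state conditions) are
#' guarded by small Boolean expressions over three kinds of atom:
#'
#' * a bare *predicate* name, true or false in the evaluation environment
#'   (co-location facts, received signals, or another region's active state);
#' * `δ(p)` — a *probabilistic* atom: one Bernoulli draw per evaluation
#'   with success probability taken from the model parameter table entry
#'   `p`;
#' * `λ(t)` — a *timed* atom: true once the entity has dwelt at least
#'   `t` steps in the transition's source state.
#'
#' Atoms combine with `&` (conjunction, binds tighter) and `|`
#' (disjunction); parentheses group. `delta(...)` and `lambda(...)` are
#' accepted as ASCII aliases and the Greek forms are emitted by
#' [format_guard()]. The empty string parses to the always-true guard used
#' for unguarded transitions.
#'
#' @name guards
NULL

GUARD_NAME_RX <- "[A-Za-z_][A-Za-z0-9_]*"

new_guard <- function(type, ...) {
  structure(list(type = type, ...), class = "dm_guard")
}

guard_true <- function() new_guard("true")

#' Tokenize guard text
#'
#' @param text guard source text
#' @return data frame of tokens with 1-based character positions
#' @noRd
guard_tokens <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    ws <- regmatches(rest, regexpr("^[ \t]+", rest))
    if (length(ws) == 1L) {
      pos <- pos + nchar(ws)
      next
    }
    rest <- substr(text, pos, n)
    one <- substr(rest, 1, 1)
    if (one %in% c("&", "|", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = one, text = one, pos = pos)
      pos <- pos + 1L
      next
    }
    if (one %in% c("δ", "λ")) {
      type <- if (one == "δ") "DELTA" else "LAMBDA"
      tokens[[length(tokens) + 1L]] <- list(type = type, text = one, pos = pos)
      pos <- pos + 1L
      next
    }
    m <- regmatches(rest, regexpr(paste0("^", GUARD_NAME_RX), rest))
    if (length(m) == 1L) {
      type <- switch(m, delta = "DELTA", lambda = "LAMBDA", "NAME")
      tokens[[length(tokens) + 1L]] <- list(type = type, text = m, pos = pos)
      pos <- pos + nchar(m)
      next
    }
    stop(guard_error(sprintf("unknown token '%s'", one), pos, text))
  }
  tokens
}

guard_error <- function(msg, pos, text) {
  structure(
    class = c("dm_guard_syntax_error", "error", "condition"),
    list(
      message = sprintf("guard syntax error at position %d: %s (in \"%s\")",
                        pos, msg, text),
      call = NULL, position = pos
    )
  )
}

#' Parse a transition guard
#'
#' Parses guard text in the grammar described in [guards] into an
#' expression tree. Parsing, printing with [format_guard()] and re-parsing
#' is the identity on the tree.
#'
#' @param text a single string; the empty string (or `NULL`) yields the
#'   always-true guard.
#' @return an object of class `dm_guard`.
#' @examples
#' parse_guard("δ(p_mature)")
#' parse_guard("A & B | C")
#' @export
parse_guard <- function(text) {
  if (is.null(text)) text <- ""
  if (inherits(text, "dm_guard")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(guard_true())
  toks <- guard_tokens(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() {
    tok <- toks[[i]]
    i <<- i + 1L
    tok
  }
  expect <- function(type) {
    tok <- peek()
    if (is.null(tok)) {
      stop(guard_error(sprintf("expected '%s' but input ended", type),
                       nchar(text) + 1L, text))
    }
    if (tok$type != type) {
      stop(guard_error(sprintf("expected '%s', found '%s'", type, tok$text),
                       tok$pos, text))
    }
    advance()
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.null(tok)) {
      stop(guard_error("expected an atom but input ended",
                       nchar(text) + 1L, text))
    }
    if (tok$type == "(") {
      advance()
      e <- parse_or()
      expect(")")
      return(e)
    }
    if (tok$type %in% c("DELTA", "LAMBDA")) {
      advance()
      expect("(")
      name <- expect("NAME")
      expect(")")
      return(new_guard(if (tok$type == "DELTA") "delta" else "lambda",
                       name = name$text))
    }
    if (tok$type == "NAME") {
      advance()
      return(new_guard("pred", name = tok$text))
    }
    stop(guard_error(sprintf("unexpected '%s'", tok$text), tok$pos, text))
  }
  parse_and <- function() {
    e <- parse_atom()
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      e <- new_guard("and", lhs = e, rhs = parse_atom())
    }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      e <- new_guard("or", lhs = e, rhs = parse_and())
    }
    e
  }
  out <- parse_or()
  tok <- peek()
  if (!is.null(tok)) {
    stop(guard_error(sprintf("unexpected '%s' after expression", tok$text),
                     tok$pos, text))
  }
  out
}

#' Print a guard back to its source syntax
#'
#' Emits the Greek `δ`/`λ` forms with the minimal parentheses
#' needed to preserve structure under the `&`-over-`|` precedence.
#'
#' @param guard a `dm_guard`
#' @return a single string; the always-true guard prints as `""`.
#' @export
format_guard <- function(guard) {
  stopifnot(inherits(guard, "dm_guard"))
  fmt <- function(g) {
    switch(g$type,
      true = "",
      pred = g$name,
      delta = sprintf("δ(%s)", g$name),
      lambda = sprintf("λ(%s)", g$name),
      and = paste(vapply(list(g$lhs, g$rhs), function(x) {
        if (x$type == "or") paste0("(", fmt(x), ")") else fmt(x)
      }, character(1)), collapse = " & "),
      or = paste(fmt(g$lhs), "|", fmt(g$rhs)),
      stop("unknown guard node type: ", g$type)
    )
  }
  fmt(guard)
}

#' @export
format.dm_guard <- function(x, ...) format_guard(x)

#' @export
print.dm_guard <- function(x, ...) {
  txt <- format_guard(x)
  cat("<guard>", if (nzchar(txt)) txt else "(always true)", "\n")
  invisible(x)
}

#' Atoms mentioned by a guard
#'
#' @param guard a `dm_guard`
#' @return list with character vectors `predicates`, `delta_params`,
#'   `lambda_params` (unique, in first-mention order).
#' @export
guard_atoms <- function(guard) {
  stopifnot(inherits(guard, "dm_guard"))
  preds <- character()
  dpar <- character()
  lpar <- character()
  walk <- function(g) {
    switch(g$type,
      pred = preds <<- c(preds, g$name),
      delta = dpar <<- c(dpar, g$name),
      lambda = lpar <<- c(lpar, g$name),
      and = { walk(g$lhs); walk(g$rhs) },
      or = { walk(g$lhs); walk(g$rhs) },
      true = NULL
    )
    invisible(NULL)
  }
  walk(guard)
  list(predicates = unique(preds), delta_params = unique(dpar),
       lambda_params = unique(lpar))
}

#' Evaluate a guard
#'
#' Predicate atoms take their value from `env`; a `δ(p)` atom makes one
#' Bernoulli draw (from the current RNG stream) with the probability bound
#' to `p` in `parameters`; a `λ(t)` atom is true iff `elapsed >= t`.
#' Both operands of every connective are evaluated (no short-circuiting),
#' so a guard mentioning the same `δ` parameter twice draws twice and
#' RNG consumption is a function of guard structure alone.
#'
#' @param guard a `dm_guard` (or guard text, parsed on the fly)
#' @param env named logical list/vector valuing every predicate atom the
#'   guard mentions
#' @param elapsed nonnegative integer: steps dwelt in the source state
#' @param parameters named numeric list/vector: the model parameter table
#' @return logical scalar
#' @export
evaluate_guard <- function(guard, env = list(), elapsed = 0L,
                           parameters = list()) {
  guard <- parse_guard(guard)
  stopifnot(is.numeric(elapsed), length(elapsed) == 1L, elapsed >= 0)
  ev <- function(g) {
    switch(g$type,
      true = TRUE,
      pred = {
        v <- env[[g$name]]
        if (is.null(v) || is.na(v)) {
          stop("guard evaluation error: predicate '", g$name,
               "' is not valued in the environment", call. = FALSE)
        }
        isTRUE(as.logical(v))
      },
      delta = {
        p <- parameters[[g$name]]
        if (is.null(p)) {
          stop("guard evaluation error: δ parameter '", g$name,
               "' is not in the parameter table", call. = FALSE)
        }
        if (!is.numeric(p) || p < 0 || p > 1) {
          stop("guard evaluation error: δ parameter '", g$name,
               "' must lie in [0, 1]", call. = FALSE)
        }
        stats::runif(1) < p
      },
      lambda = {
        t <- parameters[[g$name]]
        if (is.null(t)) {
          stop("guard evaluation error: λ parameter '", g$name,
               "' is not in the parameter table", call. = FALSE)
        }
        if (!is.numeric(t) || t < 0) {
          stop("guard evaluation error: λ parameter '", g$name,
               "' must be a nonnegative duration", call. = FALSE)
        }
        elapsed >= t
      },
      and = {
        l <- ev(g$lhs)
        r <- ev(g$rhs)
        l && r
      },
      or = {
        l <- ev(g$lhs)
        r <- ev(g$rhs)
        l || r
      },
      stop("unknown guard node type: ", g$type)
    )
  }
  ev(guard)
}

#' Can a guard be satisfied under partial knowledge?
#'
#' Used by the static consistency checker: predicate atoms named in `fixed`
#' take the given value; every other atom (predicates not fixed, and all
#' `δ`/`λ` atoms) is treated as free. Returns `TRUE` iff some
#' assignment of the free atoms makes the guard true (brute-force
#' enumeration; guards are small).
#'
#' @param guard a `dm_guard` or guard text
#' @param fixed named logical vector of pinned predicate values
#' @return logical scalar
#' @export
guard_satisfiable <- function(guard, fixed = c()) {
  guard <- parse_guard(guard)
  atoms <- guard_atoms(guard)
  free_preds <- setdiff(atoms$predicates, names(fixed))
  # delta/lambda atoms are identified by (kind, position-free name); a
  # repeated name is one unknown, which is conservative either way
  free <- c(free_preds,
            paste0(".delta.", atoms$delta_params),
            paste0(".lambda.", atoms$lambda_params))
  ev_with <- function(vals) {
    ev <- function(g) {
      switch(g$type,
        true = TRUE,
        pred = if (g$name %in% names(fixed)) isTRUE(fixed[[g$name]])
               else isTRUE(vals[[g$name]]),
        delta = isTRUE(vals[[paste0(".delta.", g$name)]]),
        lambda = isTRUE(vals[[paste0(".lambda.", g$name)]]),
        and = ev(g$lhs) && ev(g$rhs),
        or = ev(g$lhs) || ev(g$rhs)
      )
    }
    ev(guard)
  }
  if (length(free) == 0L) return(ev_with(list()))
  for (mask in seq_len(2^length(free)) - 1L) {
    bits <- as.logical(bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L))
    vals <- stats::setNames(as.list(bits), free)
    if (ev_with(vals)) return(TRUE)
  }
  FALSE
}
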