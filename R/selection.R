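#' Atom selections
#'
#' A small deterministic selection language resolves named atom sets on a
#' topology. Clauses: `resname X ...`, `resid N` or `resid N:M`, `name X ...`,
#' `subunit X ...`, `element X ...`, plus the bare keywords `backbone`
#' (names N, CA, C, O and the amide HN) and `sidechain` (non-backbone heavy
#' atoms, C-beta included). Clauses combine with `and`, `or`, `not` and
#' parentheses; `and` binds tighter than `or`.
#'
#' @param topology a [topology] object
#' @param expression selection expression
#' @return object of class `selection` with the expression and the resolved
#'   0-based `indices`; an empty result triggers a warning, not an error
#' @examples
#' \dontrun{
#' select(top, "resid 59 and name OG1")
#' select(top, "subunit A and (resid 81 or resid 85)")
#' }
#' @export
select <- function(topology, expression) {
  stopifnot(inherits(topology, "topology"))
  mask <- eval_selection(topology$atoms, expression)
  idx <- topology$atoms$atom_id[mask]
  if (length(idx) == 0L)
    warning("empty selection: '", expression, "'", call. = FALSE)
  structure(list(expression = expression, indices = idx), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("<selection> '%s': %d atoms\n", x$expression, length(x$indices)))
  invisible(x)
}

#' Convenience selections for the channel architecture
#'
#' @param topology a [topology]
#' @param which one of "filter" (TVGYG residues), "inner_helix",
#'   "outer_helix", "backbone", "sidechain"
#' @param config a [channel_config()] supplying the residue intervals
#' @return a `selection`
#' @export
named_selection <- function(topology,
                            which = c("filter", "inner_helix", "outer_helix",
                                      "backbone", "sidechain"),
                            config = channel_config()) {
  which <- match.arg(which)
  expr <- switch(which,
    filter = sprintf("resid %d:%d", config$filter_resids[1], config$filter_resids[2]),
    inner_helix = sprintf("resid %d:%d", config$inner_helix[1], config$inner_helix[2]),
    outer_helix = sprintf("resid %d:%d", config$outer_helix[1], config$outer_helix[2]),
    backbone = "backbone",
    sidechain = "sidechain")
  select(topology, expr)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O", "HN", "OXT")

# --- tokenizer -------------------------------------------------------------

tokenize_selection <- function(expression) {
  chars <- strsplit(expression, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(text = ch, pos = i)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("[\\s()]", chars[j], perl = TRUE)) j <- j + 1L
    toks[[length(toks) + 1L]] <-
      list(text = paste(chars[i:(j - 1L)], collapse = ""), pos = i)
    i <- j
  }
  toks
}

sel_error <- function(msg, tok) {
  pos <- if (is.null(tok)) "end of expression" else sprintf("position %d", tok$pos)
  stop(sprintf("selection parse error at %s: %s", pos, msg), call. = FALSE)
}

# --- recursive-descent parser ---------------------------------------------
# expr := term ('or' term)* ; term := factor ('and' factor)*
# factor := 'not' factor | '(' expr ')' | clause

eval_selection <- function(atoms, expression) {
  st <- new.env(parent = emptyenv())
  st$toks <- tokenize_selection(expression)
  st$i <- 1L
  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() { tok <- peek(); st$i <- st$i + 1L; tok }
  keywords <- c("and", "or", "not", "(", ")")
  clause_kw <- c("resname", "resid", "name", "subunit", "element")

  parse_values <- function(kw) {
    vals <- character()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$text %in% keywords || tok$text %in% clause_kw)
        break
      vals <- c(vals, advance()$text)
    }
    if (length(vals) == 0L)
      sel_error(sprintf("keyword '%s' needs at least one value", kw), peek())
    vals
  }

  clause_mask <- function(kw, vals) {
    switch(kw,
      resname = atoms$residue_name %in% vals,
      name = atoms$atom_name %in% vals,
      subunit = atoms$subunit %in% vals,
      element = toupper(atoms$element) %in% toupper(vals),
      resid = {
        m <- rep(FALSE, nrow(atoms))
        for (v in vals) {
          if (grepl("^-?[0-9]+:-?[0-9]+$", v)) {
            rng <- as.integer(strsplit(v, ":")[[1]])
            m <- m | (atoms$residue_id >= rng[1] & atoms$residue_id <= rng[2])
          } else if (grepl("^-?[0-9]+$", v)) {
            m <- m | atoms$residue_id == as.integer(v)
          } else sel_error(sprintf("bad resid value '%s'", v), NULL)
        }
        m
      })
  }

  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) sel_error("unexpected end of expression", NULL)
    if (tok$text == "not") { advance(); return(!parse_factor()) }
    if (tok$text == "(") {
      advance()
      m <- parse_expr()
      close_tok <- peek()
      if (is.null(close_tok) || close_tok$text != ")")
        sel_error("expected ')'", close_tok)
      advance()
      return(m)
    }
    if (tok$text %in% clause_kw) {
      advance()
      return(clause_mask(tok$text, parse_values(tok$text)))
    }
    if (tok$text == "backbone") { advance(); return(atoms$atom_name %in% BACKBONE_NAMES) }
    if (tok$text == "sidechain") {
      advance()
      return(!(atoms$atom_name %in% BACKBONE_NAMES) & toupper(atoms$element) != "H")
    }
    if (tok$text == "all") { advance(); return(rep(TRUE, nrow(atoms))) }
    sel_error(sprintf("unexpected token '%s'", tok$text), tok)
  }

  parse_term <- function() {
    m <- parse_factor()
    while (!is.null(peek()) && peek()$text == "and") {
      advance()
      m <- m & parse_factor()
    }
    m
  }

  parse_expr <- function() {
    m <- parse_term()
    while (!is.null(peek()) && peek()$text == "or") {
      advance()
      m <- m | parse_term()
    }
    m
  }

  m <- parse_expr()
  if (st$i <= length(st$toks))
    sel_error(sprintf("trailing input '%s'", peek()$text), peek())
  m
}
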