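# Atom selection mini-grammar.
#
#   expr    := term ('or' term)*
#   term    := factor ('and' factor)*
#   factor  := 'not' factor | '(' expr ')' | primary
#   primary := 'name' V | 'element' V | 'resname' V | 'chain' V
#            | 'resid' N | 'resid' N:M | 'all' | 'none' | 'ions'
#            | 'nucleic' | 'heavy'
#
# Values are single whitespace-delimited tokens (primes allowed: O2', C1').
# Resolution is deterministic, order-independent and idempotent.

sel_tokenize <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Resolve an atom selection expression
#'
#' @param model an [rna_model()].
#' @param expr selection string, e.g. `"name P"`, `"chain A and resid 2:9"`,
#'   `"resname K+"`, `"nucleic and heavy"`, `"not ions"`.
#' @return sorted integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(model, expr) {
  if (is.numeric(expr)) return(sort(unique(as.integer(expr))))
  atoms <- model$atoms
  toks <- sel_tokenize(expr)
  if (length(toks) == 0) stop("selection grammar error: empty expression")
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  bad <- function(tok, at = pos) {
    stop(sprintf("selection grammar error at token %d: unexpected '%s'",
                 at, tok))
  }
  need_value <- function(kw) {
    v <- advance()
    if (is.na(v) || v %in% c("(", ")", "and", "or", "not"))
      stop(sprintf("selection grammar error: keyword '%s' needs a value", kw))
    v
  }

  is_nucleic <- atoms$resname %in% names(RESNAME_MAP)
  primary <- function() {
    tok <- advance()
    if (is.na(tok)) stop("selection grammar error: unexpected end of expression")
    switch(tok,
      "all" = rep(TRUE, nrow(atoms)),
      "none" = rep(FALSE, nrow(atoms)),
      "ions" = atoms$resname %in% ION_RESNAMES,
      "nucleic" = is_nucleic,
      "heavy" = atoms$element != "H",
      "name" = atoms$name == need_value("name"),
      "element" = ,
      "elem" = atoms$element == toupper(need_value("element")),
      "resname" = atoms$resname == need_value("resname"),
      "chain" = atoms$chain == need_value("chain"),
      "resid" = {
        v <- need_value("resid")
        m <- regmatches(v, regexec("^(-?[0-9]+)(?:[:\\-](-?[0-9]+))?$", v))[[1]]
        if (length(m) == 0 || !nzchar(m[1]))
          stop(sprintf("selection grammar error: bad residue range '%s'", v))
        lo <- as.integer(m[2])
        hi <- if (nzchar(m[3])) as.integer(m[3]) else lo
        atoms$resid >= lo & atoms$resid <= hi
      },
      "(" = {
        v <- expr_rule()
        if (!identical(advance(), ")"))
          stop("selection grammar error: missing closing parenthesis")
        v
      },
      bad(tok, at = pos - 1L)
    )
  }
  factor_rule <- function() {
    if (identical(peek(), "not")) {
      advance()
      return(!factor_rule())
    }
    primary()
  }
  term_rule <- function() {
    v <- factor_rule()
    while (identical(peek(), "and")) {
      advance()
      v <- v & factor_rule()
    }
    v
  }
  expr_rule <- function() {
    v <- term_rule()
    while (identical(peek(), "or")) {
      advance()
      v <- v | term_rule()
    }
    v
  }

  mask <- expr_rule()
  if (pos <= length(toks)) bad(peek())
  which(mask)
}
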