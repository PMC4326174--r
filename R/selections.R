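# Atom-selection mini-grammar.
#
#   expr      := and-expr ('or' and-expr)*
#   and-expr  := not-expr ('and' not-expr)*
#   not-expr  := 'not' not-expr | '(' expr ')' | predicate
#   predicate := 'all' | 'heavy' | 'calpha' | 'solvent'
#              | 'chain' token+ | 'resname' token+ | 'name' token+
#              | 'resid' range+          where range := INT | INT-INT
#
# 'heavy' keeps atoms whose element is not hydrogen (H/D); 'calpha' is
# shorthand for protein alpha-carbons (atom name CA, element C);
# 'solvent' matches common water and monatomic-ion residue names so
# protein selections can exclude them with 'and not solvent'.

.sel_keywords <- c("all", "heavy", "calpha", "solvent", "chain",
                   "resname", "name", "resid", "and", "or", "not",
                   "(", ")")

.sel_solvent_resnames <- c("HOH", "WAT", "TIP3", "SOL",
                           "NA", "SOD", "CL", "CLA", "K", "POT")

.sel_tokenize <- function(expression) {
  s <- gsub("\\(", " ( ", expression)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

# recursive-descent parser; returns a function(atoms) -> logical mask
.sel_parse <- function(toks) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  fail <- function(msg) stop("selection parse error: ", msg, call. = FALSE)

  take_values <- function(kind) {
    vals <- character(0)
    while (!is.na(peek()) && !(tolower(peek()) %in% .sel_keywords)) {
      vals <- c(vals, advance())
    }
    if (!length(vals)) fail(paste0("'", kind, "' needs at least one value"))
    vals
  }

  parse_predicate <- function() {
    t <- advance()
    kw <- tolower(t)
    if (kw == "all") return(function(a) rep(TRUE, nrow(a)))
    if (kw == "heavy")
      return(function(a) !toupper(a$element) %in% c("H", "D"))
    if (kw == "calpha")
      return(function(a) a$name == "CA" & toupper(a$element) == "C")
    if (kw == "solvent")
      return(function(a) toupper(a$resname) %in% .sel_solvent_resnames)
    if (kw == "chain") {
      v <- take_values("chain")
      return(function(a) a$chain %in% v)
    }
    if (kw == "resname") {
      v <- toupper(take_values("resname"))
      return(function(a) toupper(a$resname) %in% v)
    }
    if (kw == "name") {
      v <- toupper(take_values("name"))
      return(function(a) toupper(a$name) %in% v)
    }
    if (kw == "resid") {
      v <- take_values("resid")
      keep <- integer(0)
      for (item in v) {
        if (grepl("^[0-9]+-[0-9]+$", item)) {
          m <- regmatches(item, regexec("^([0-9]+)-([0-9]+)$", item))[[1L]]
          lo <- as.integer(m[2L]); hi <- as.integer(m[3L])
          if (is.na(lo) || is.na(hi) || lo > hi)
            fail(paste0("bad residue range '", item, "'"))
          keep <- c(keep, lo:hi)
        } else if (grepl("^-?[0-9]+$", item)) {
          keep <- c(keep, as.integer(item))
        } else fail(paste0("bad residue id '", item, "'"))
      }
      return(function(a) a$resno %in% keep)
    }
    fail(paste0("unexpected token '", t, "'"))
  }

  parse_not <- function() {
    if (!is.na(peek()) && tolower(peek()) == "not") {
      advance()
      f <- parse_not()
      return(function(a) !f(a))
    }
    if (!is.na(peek()) && peek() == "(") {
      advance()
      f <- parse_or()
      if (is.na(peek()) || peek() != ")") fail("missing ')'")
      advance()
      return(f)
    }
    if (is.na(peek())) fail("unexpected end of expression")
    parse_predicate()
  }

  parse_and <- function() {
    f <- parse_not()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      g <- parse_not()
      ff <- f; f <- local({ a1 <- ff; b1 <- g
        function(a) a1(a) & b1(a) })
    }
    f
  }

  parse_or <- function() {
    f <- parse_and()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      g <- parse_and()
      ff <- f; f <- local({ a1 <- ff; b1 <- g
        function(a) a1(a) | b1(a) })
    }
    f
  }

  f <- parse_or()
  if (!is.na(peek())) fail(paste0("trailing token '", peek(), "'"))
  f
}

#' Resolve an atom selection on a structure
#'
#' Evaluates a selection expression against a [MolStructure-class] and
#' returns the matching atom indices, in file order.  The grammar
#' combines the predicates `chain`, `resid` (single ids or `lo-hi`
#' ranges), `resname`, `name`, `heavy` (non-hydrogen by element),
#' `calpha`, `solvent` and `all` with `and`, `or`, `not` and
#' parentheses; `not` binds tightest, then `and`, then `or`.
#'
#' Resolution is a pure function of the expression and the structure:
#' repeated calls return identical index vectors.  An expression that
#' matches no atom is an error, as is a malformed expression.
#'
#' @param expression selection string, e.g.
#'   `"resid 81-89 and name CA"`.
#' @param structure a [MolStructure-class].
#' @return integer vector of 1-based atom indices, increasing.
#' @examples
#' s <- buildToy()$structure
#' length(resolveSelection("resid 81-89 and name CA", s))
#' @export
resolveSelection <- function(expression, structure) {
  stopifnot(is.character(expression), length(expression) == 1L)
  if (!is(structure, "MolStructure"))
    stop("'structure' must be a MolStructure")
  toks <- .sel_tokenize(expression)
  if (!length(toks)) stop("selection parse error: empty expression",
                          call. = FALSE)
  mask <- .sel_parse(toks)(structure@atoms)
  idx <- which(mask)
  if (!length(idx))
    stop("selection '", expression, "' matches no atoms", call. = FALSE)
  idx
}
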