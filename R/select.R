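#' Select atoms with a small selection expression language
#'
#' Selections are the plumbing between the data model and every analysis:
#' "backbone atoms", "non-hydrogen atoms", "tube atoms" and the like.
#' The expression language supports the primitives
#' \itemize{
#'   \item \code{group:receptor} (one of receptor/tube/solvent/ligand/other)
#'   \item \code{element:C} or \code{element:C,N,O}
#'   \item \code{name:N,CA,C,O} (atom-name set)
#'   \item \code{resid:12} / \code{resid:5-10} / \code{resid:5-10,14}
#'   \item \code{resname:HOH,WAT}
#'   \item \code{chain:A}
#'   \item \code{backbone} (atom names N, CA, C, O)
#'   \item \code{heavy} (element != H)
#'   \item \code{all}
#' }
#' combined with \code{and}, \code{or}, \code{not} and parentheses;
#' \code{and} binds tighter than \code{or}.
#'
#' @param system a \code{mol_system}.
#' @param expr selection expression string, or an integer vector of atom
#'   indices (passed through after validation).
#' @param label optional label stored on the selection (defaults to the
#'   expression text).
#' @return Object of class \code{atom_selection}: list with \code{label}
#'   and \code{indices} (sorted unique 1-based atom indices).
#' @examples
#' sys <- mol_system(data.frame(
#'   name = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
#'   resid = 1L, resname = "ALA"))
#' select_atoms(sys, "backbone")$indices  # 1 2 3 4
#' @export
select_atoms <- function(system, expr, label = NULL) {
  stopifnot(inherits(system, "mol_system"))
  if (is.numeric(expr)) {
    idx <- sort(unique(as.integer(expr)))
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > n_atoms(system)))
      stop("selection indices out of range")
    return(structure(list(label = label %||% "indices", indices = idx),
                     class = "atom_selection"))
  }
  stopifnot(is.character(expr), length(expr) == 1)
  mask <- eval_selection(system$atoms, expr)
  structure(list(label = label %||% expr, indices = which(mask)),
            class = "atom_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

# --- expression evaluation: tokenize, then recursive descent -------------

tokenize_selection <- function(expr) {
  pat <- "\\(|\\)|[A-Za-z_]+:[^ ()]+|[A-Za-z_]+"
  m <- gregexpr(pat, expr)[[1]]
  if (m[1] == -1) stop("empty selection expression")
  toks <- regmatches(expr, gregexpr(pat, expr))[[1]]
  covered <- sum(attr(m, "match.length"))
  residual <- gsub("\\s", "", gsub(pat, "", expr))
  if (nchar(residual) > 0)
    stop("cannot parse selection near: '", residual, "'")
  toks
}

eval_selection <- function(atoms, expr) {
  toks <- tokenize_selection(expr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }

  parse_or <- function() {
    left <- parse_and()
    while (!is.na(peek()) && identical(tolower(peek()), "or")) {
      advance()
      left <- left | parse_and()
    }
    left
  }
  parse_and <- function() {
    left <- parse_unary()
    while (!is.na(peek()) && identical(tolower(peek()), "and")) {
      advance()
      left <- left & parse_unary()
    }
    left
  }
  parse_unary <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of selection expression")
    if (identical(tolower(t), "not")) {
      advance()
      return(!parse_unary())
    }
    if (identical(t, "(")) {
      advance()
      v <- parse_or()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in selection")
      advance()
      return(v)
    }
    advance()
    eval_primitive(atoms, t)
  }

  out <- parse_or()
  if (pos <= length(toks))
    stop("trailing tokens in selection expression: ",
         paste(toks[pos:length(toks)], collapse = " "))
  out
}

eval_primitive <- function(atoms, tok) {
  lt <- tolower(tok)
  if (lt == "all") return(rep(TRUE, nrow(atoms)))
  if (lt == "heavy") return(toupper(atoms$element) != "H")
  if (lt == "backbone")
    return(atoms$name %in% c("N", "CA", "C", "O"))
  if (!grepl(":", tok))
    stop("unknown selection keyword: '", tok, "'")
  key <- tolower(sub(":.*", "", tok))
  val <- sub("^[^:]*:", "", tok)
  parts <- strsplit(val, ",", fixed = TRUE)[[1]]
  switch(key,
    group = atoms$group %in% parts,
    element = toupper(atoms$element) %in% toupper(parts),
    name = atoms$name %in% parts,
    resname = atoms$resname %in% parts,
    chain = atoms$chain %in% parts,
    resid = atoms$resid %in% expand_ranges(parts),
    stop("unknown selection key: '", key, "'")
  )
}

expand_ranges <- function(parts) {
  out <- integer(0)
  for (p in parts) {
    if (grepl("^-?[0-9]+--?[0-9]+$", p) && grepl("[0-9]-", p)) {
      ab <- as.integer(strsplit(sub("([0-9])-", "\\1 ", p), " ")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else stop("bad resid range: '", p, "'")
  }
  out
}
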