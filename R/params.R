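#' Read a per-atom parameter table
#'
#' Delimited text (tab, comma or whitespace) with header columns
#' \code{atom_name}, \code{residue_name}, \code{radius} (Angstrom),
#' \code{charge} (e), \code{epsilon} (kcal/mol), \code{sigma} (Angstrom).
#' The residue name \code{*} is a wildcard matched when no exact
#' (residue, atom) row exists.
#'
#' @param path file path.
#' @return object of class \code{param_table} (the validated data.frame).
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) == 1) # comma-delimited fallback
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("atom_name", "residue_name", "radius", "charge", "epsilon", "sigma")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("parameter table format error: missing column(s): ",
         paste(miss, collapse = ", "))
  key <- paste(df$residue_name, df$atom_name)
  if (anyDuplicated(key))
    stop("parameter table format error: duplicate entry for (",
         key[duplicated(key)][1], ")")
  for (col in c("radius", "charge", "epsilon", "sigma")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]))
      stop("parameter table format error: non-numeric ", col)
  }
  structure(df, class = c("param_table", "data.frame"))
}

#' Apply a parameter table to a system
#'
#' Fills the \code{radius}, \code{charge}, \code{epsilon}, \code{sigma}
#' atom columns by (residue_name, atom_name) lookup, falling back to the
#' wildcard residue \code{*}. Any atom without a match raises an
#' unparameterized-atom error.
#'
#' @param system a \code{mol_system}.
#' @param params a \code{param_table} from \code{\link{read_parameter_table}}.
#' @return the system with parameter columns filled.
#' @export
apply_parameters <- function(system, params) {
  stopifnot(inherits(system, "mol_system"), inherits(params, "param_table"))
  a <- system$atoms
  exact <- match(paste(a$resname, a$name), paste(params$residue_name, params$atom_name))
  wild <- match(paste("*", a$name), paste(params$residue_name, params$atom_name))
  row <- ifelse(is.na(exact), wild, exact)
  if (anyNA(row)) {
    i <- which(is.na(row))[1]
    stop(sprintf("unparameterized atom: %s/%s (atom %d)",
                 a$resname[i], a$name[i], i))
  }
  for (col in c("radius", "charge", "epsilon", "sigma"))
    a[[col]] <- params[[col]][row]
  system$atoms <- a
  system
}

#' Write a parameter table
#' @param params a \code{param_table} or data.frame with the table columns.
#' @param path output path (tab-delimited).
#' @return \code{path}, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
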