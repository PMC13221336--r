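# Compound table input.

#' Parse a compound table
#'
#' Reads a delimited text table with columns `id`, `name`, `cas`, `smiles`
#' (any column order, extra columns ignored) and returns a validated compound
#' panel. Every SMILES is parsed; an unparseable SMILES or a duplicated id is
#' a row-level error that names the offending compound.
#'
#' @param table path to a CSV file, or a character vector of CSV lines, or a
#'   data.frame already holding the four columns.
#' @return an object of class `nv_panel`: a list of compounds, each a list
#'   with `id`, `name`, `cas`, `smiles` and the parsed molecule `mol`.
#' @examples
#' panel <- parse_compound_table(nitrostyrene_panel_file())
#' length(panel)
#' @export
parse_compound_table <- function(table) {
  df <- if (is.data.frame(table)) {
    table
  } else if (is.character(table) && length(table) == 1L && file.exists(table)) {
    utils::read.csv(table, stringsAsFactors = FALSE)
  } else if (is.character(table)) {
    utils::read.csv(text = table, stringsAsFactors = FALSE)
  } else {
    stop("table must be a file path, CSV text, or a data.frame", call. = FALSE)
  }
  names(df) <- tolower(trimws(names(df)))
  required <- c("id", "name", "cas", "smiles")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("compound table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(df)) return(structure(list(), class = "nv_panel"))
  ids <- suppressWarnings(as.integer(df$id))
  if (anyNA(ids) || any(ids <= 0L)) {
    stop("compound ids must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    smi <- trimws(df$smiles[i])
    mol <- tryCatch(nv_parse_smiles(smi), error = function(e) e)
    if (inherits(mol, "error")) {
      stop("compound id ", ids[i], ": invalid SMILES '", smi, "' (",
           conditionMessage(mol), ")", call. = FALSE)
    }
    if (sum(mol$Z > 1) < 1L) {
      stop("compound id ", ids[i], ": molecule has no heavy atoms",
           call. = FALSE)
    }
    comp <- nv_components(mol)
    if (length(unique(comp)) != 1L) {
      stop("compound id ", ids[i], ": SMILES is not a connected molecule",
           call. = FALSE)
    }
    out[[i]] <- structure(
      list(id = ids[i], name = as.character(df$name[i]),
           cas = as.character(df$cas[i]), smiles = smi, mol = mol),
      class = "nv_compound")
  }
  structure(out, class = "nv_panel")
}

#' Path to the packaged nine-compound beta-nitrostyrene panel
#'
#' The panel of nine compounds (lead structure beta-nitrostyrene plus eight
#' structural derivatives chosen to probe the nitrovinyl, nitro, vinyl and
#' phenyl-substitution features) that the assay modules were designed around.
#'
#' @return path to the packaged CSV file with columns id, name, cas, smiles.
#' @export
nitrostyrene_panel_file <- function() {
  system.file("extdata", "nitrostyrene_panel.csv", package = "nitrotox",
              mustWork = TRUE)
}

#' Load the packaged nine-compound panel
#'
#' @return an `nv_panel` as from [parse_compound_table()].
#' @export
nitrostyrene_panel <- function() {
  parse_compound_table(nitrostyrene_panel_file())
}

#' @export
`[.nv_panel` <- function(x, i) {
  structure(unclass(x)[i], class = "nv_panel")
}

#' @export
print.nv_panel <- function(x, ...) {
  cat("<nv_panel> ", length(x), " compounds\n", sep = "")
  for (c in x) cat(sprintf("  %2d  %-42s %s\n", c$id, c$name, c$smiles))
  invisible(x)
}

panel_ids <- function(panel) vapply(panel, function(c) c$id, integer(1))
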