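# Tanimoto similarity, panel similarity matrices, similarity ranking against
# a lead structure, and the rule-based panel selection report.

#' Tanimoto coefficient of two fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bits. Both fingerprints must be of
#' the same kind. Convention for degenerate inputs (documented): two empty
#' fingerprints have similarity 1.0; one empty fingerprint gives 0.0.
#'
#' @param a,b `nv_fingerprint` objects of the same kind.
#' @return Tanimoto coefficient in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "nv_fingerprint"), inherits(b, "nv_fingerprint"))
  if (!identical(a$kind, b$kind)) {
    stop("fingerprint kind mismatch: ", a$kind, " vs ", b$kind, call. = FALSE)
  }
  na <- length(a$on_bits); nb <- length(b$on_bits)
  if (na == 0L && nb == 0L) return(1)
  if (na == 0L || nb == 0L) return(0)
  i <- length(intersect(a$on_bits, b$on_bits))
  i / (na + nb - i)
}

#' Pairwise Tanimoto similarity matrix of a compound panel
#'
#' @param panel an `nv_panel` (>= 2 compounds).
#' @param kind fingerprint kind, see [fingerprint()].
#' @return an `nv_simmatrix`: list with `kind`, `ids` and the symmetric
#'   `values` matrix (unit diagonal for non-empty fingerprints).
#' @export
similarity_matrix <- function(panel, kind = "pubchem881") {
  stopifnot(inherits(panel, "nv_panel"))
  if (length(panel) < 2L) {
    stop("similarity matrix needs at least 2 compounds", call. = FALSE)
  }
  ids <- panel_ids(panel)
  fps <- lapply(panel, function(cp) fingerprint(cp$mol, kind))
  n <- length(panel)
  vals <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    vals[i, i] <- tanimoto(fps[[i]], fps[[i]])
    if (i < n) {
      for (j in (i + 1):n) {
        tc <- tanimoto(fps[[i]], fps[[j]])
        vals[i, j] <- tc; vals[j, i] <- tc
      }
    }
  }
  structure(list(kind = kind, ids = ids, values = vals),
            class = "nv_simmatrix")
}

#' @export
print.nv_simmatrix <- function(x, ...) {
  cat("<nv_simmatrix> ", x$kind, ", ", length(x$ids), " compounds\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' Rank panel compounds by similarity to a reference compound
#'
#' Orders all compounds (including the reference itself) by descending
#' Tanimoto coefficient against the reference; ties are broken by ascending
#' compound id.
#'
#' @param m an `nv_simmatrix`.
#' @param ref_id id of the reference compound (must be in `m$ids`).
#' @return data.frame with columns `id`, `tc`, ordered as described.
#' @export
rank_by_reference <- function(m, ref_id) {
  stopifnot(inherits(m, "nv_simmatrix"))
  pos <- match(ref_id, m$ids)
  if (is.na(pos)) stop("unknown reference id: ", ref_id, call. = FALSE)
  tc <- m$values[, pos]
  ord <- order(-tc, m$ids)
  data.frame(id = m$ids[ord], tc = unname(tc[ord]))
}

# default structural rules of the panel design: the nitrovinyl moiety (the
# conjugated C=C-NO2 group, the toxicity-driving feature), its component
# groups, and the carboxyl replacement
nv_default_rules <- function() {
  c(
    nitrovinyl = "C=C[N+](=O)[O-]",
    nitro = "[N+](=O)[O-]",
    vinyl = "C=C",
    phenyl = "c1ccccc1",
    carboxyl = "C(=O)[OX2H1]"
  )
}

#' Rule-based panel selection report
#'
#' Evaluates a set of named SMARTS substructure rules on every panel member
#' and reports the boolean flags next to the Tanimoto similarity to a
#' reference compound. The default rule set encodes the structural logic of
#' the beta-nitrostyrene panel: presence of the nitrovinyl moiety, the nitro
#' group, a vinyl group, a phenyl ring and a carboxyl group.
#'
#' @param panel an `nv_panel`.
#' @param ref_id reference compound id for the similarity column.
#' @param rules named character vector of SMARTS; default
#'   [nv_default_rules()]-equivalent set.
#' @param kind fingerprint kind for the similarity column.
#' @return data.frame with `id`, `name`, `tc`, then one logical column per
#'   rule, ordered by descending `tc` (ties by id).
#' @export
selection_report <- function(panel, ref_id = 1L, rules = NULL,
                             kind = "pubchem881") {
  stopifnot(inherits(panel, "nv_panel"))
  if (is.null(rules)) rules <- nv_default_rules()
  if (is.null(names(rules)) || any(!nzchar(names(rules)))) {
    stop("rules must be a named character vector of SMARTS", call. = FALSE)
  }
  pats <- lapply(seq_along(rules), function(i) {
    tryCatch(nv_smarts(rules[[i]]), error = function(e) {
      stop("invalid SMARTS for rule '", names(rules)[i], "': ",
           conditionMessage(e), call. = FALSE)
    })
  })
  names(pats) <- names(rules)
  m <- similarity_matrix(panel, kind)
  ranked <- rank_by_reference(m, ref_id)
  names_by_id <- stats::setNames(vapply(panel, function(cp) cp$name,
                                        character(1)), panel_ids(panel))
  mols_by_id <- stats::setNames(lapply(panel, function(cp) cp$mol),
                                panel_ids(panel))
  flags <- lapply(names(pats), function(nm) {
    vapply(as.character(ranked$id), function(id) {
      length(nv_match(mols_by_id[[id]], pats[[nm]], first_only = TRUE)) > 0L
    }, logical(1))
  })
  names(flags) <- names(pats)
  out <- cbind(
    data.frame(id = ranked$id,
               name = unname(names_by_id[as.character(ranked$id)]),
               tc = ranked$tc),
    as.data.frame(flags)
  )
  rownames(out) <- NULL
  out
}
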