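#' Linkage codes and their integer weights
#'
#' The knowledge base expresses the strength of association between a symptom
#' and a disease or brain zone as a categorical linkage code, each mapped to a
#' fixed integer weight:
#'
#' \tabular{lll}{
#'   code \tab weight \tab meaning \cr
#'   NEV  \tab -3 \tab symptom practically never occurs with the disease \cr
#'   OTTD \tab -2 \tab occurrence points to a different disease \cr
#'   UL   \tab -1 \tab unlikely with the disease \cr
#'   N    \tab  0 \tab no linkage \cr
#'   Y    \tab +1 \tab symptom occurs with the disease \cr
#'   R    \tab +1 \tab related (brain-zone matrices only) \cr
#'   HR   \tab +2 \tab highly related: presence adds two points instead of one
#' }
#'
#' The negative codes (NEV, OTTD, UL) and Y are valid only in disease
#' matrices; R only in brain-zone matrices; N and HR in both.  Cells may also
#' hold bare integers in \code{[-3, 4]} (the full arithmetic range the scoring
#' rules use), for weights with no single canonical code.
#'
#' @format Named integer vector, code -> weight.
#' @export
linkage_codes <- c(NEV = -3L, OTTD = -2L, UL = -1L, N = 0L, Y = 1L, R = 1L,
                   HR = 2L)

.codes_for_kind <- function(entity_kind) {
  if (entity_kind == "DISEASE") c("NEV", "OTTD", "UL", "N", "Y", "HR")
  else c("N", "R", "HR")
}

.weight_range <- function(entity_kind) {
  if (entity_kind == "DISEASE") c(-3L, 4L) else c(0L, 4L)
}

#' Construct a knowledge base
#'
#' A knowledge base is the entire medical content of the scoring algorithm:
#' an entities-by-symptoms matrix of integer linkage weights, together with
#' the symptom catalog (and its general / ocular motor grouping) and the
#' entity kind (\code{"DISEASE"} or \code{"BRAIN_ZONE"}).
#'
#' @param weights integer matrix, rows = entities, columns = symptoms, with
#'   dimnames.  Missing values are not allowed; absent linkage is weight 0.
#' @param entity_kind \code{"DISEASE"} or \code{"BRAIN_ZONE"}.
#' @param symptom_groups optional character vector (one of \code{"GENERAL"},
#'   \code{"OCULOMOTOR"} per symptom, named by symptom).  Defaults to
#'   \code{"GENERAL"} for all.
#' @return An object of class \code{knowledge_base} with elements
#'   \code{weights}, \code{entity_kind}, \code{entities}, \code{symptoms},
#'   \code{symptom_groups}.
#' @export
knowledge_base <- function(weights, entity_kind = c("DISEASE", "BRAIN_ZONE"),
                           symptom_groups = NULL) {
  entity_kind <- match.arg(entity_kind)
  if (!is.matrix(weights) || is.null(rownames(weights)) ||
      is.null(colnames(weights)))
    stop("`weights` must be a matrix with entity rownames and symptom colnames")
  storage.mode(weights) <- "integer"
  if (anyNA(weights)) stop("`weights` must not contain NA")
  if (is.null(symptom_groups))
    symptom_groups <- stats::setNames(rep("GENERAL", ncol(weights)),
                                      colnames(weights))
  symptom_groups <- symptom_groups[colnames(weights)]
  kb <- structure(
    list(weights = weights,
         entity_kind = entity_kind,
         entities = rownames(weights),
         symptoms = colnames(weights),
         symptom_groups = symptom_groups),
    class = "knowledge_base")
  findings <- validate_knowledge_base(kb)
  if (length(findings))
    stop("invalid knowledge base:\n  ", paste(findings, collapse = "\n  "))
  kb
}

#' Validate a knowledge base
#'
#' Checks every structural invariant and returns findings rather than
#' throwing: unique non-empty symptom and entity identifiers, integer weights
#' within the arithmetic range \code{[-3, 4]}, and non-negative weights for
#' brain-zone matrices (zone linkage codes are N/R/HR only).
#'
#' @param kb a \code{knowledge_base} (or an unvalidated list shaped like one).
#' @return Character vector of findings; empty (length 0) iff the knowledge
#'   base is valid.
#' @export
validate_knowledge_base <- function(kb) {
  findings <- character()
  w <- kb$weights
  if (length(kb$symptoms) < 1L)
    findings <- c(findings, "symptom catalog is empty")
  dup <- unique(kb$symptoms[duplicated(kb$symptoms)])
  if (length(dup))
    findings <- c(findings, paste0("duplicate symptom id: ", dup))
  dup <- unique(kb$entities[duplicated(kb$entities)])
  if (length(dup))
    findings <- c(findings, paste0("duplicate entity id: ", dup))
  if (any(!nzchar(trimws(kb$symptoms))))
    findings <- c(findings, "empty symptom id")
  rng <- .weight_range(kb$entity_kind)
  bad <- which(w < rng[1] | w > rng[2], arr.ind = TRUE)
  if (nrow(bad)) {
    findings <- c(findings, sprintf(
      "weight %d out of range [%d, %d] for %s at cell (%s, %s)",
      w[bad], rng[1], rng[2], kb$entity_kind,
      rownames(w)[bad[, 1]], colnames(w)[bad[, 2]]))
  }
  if (!all(kb$symptom_groups %in% c("GENERAL", "OCULOMOTOR"), na.rm = FALSE) ||
      anyNA(kb$symptom_groups))
    findings <- c(findings, "symptom groups must be GENERAL or OCULOMOTOR")
  findings
}

#' Translate linkage code tokens to integer weights
#'
#' Accepts canonical codes valid for the matrix kind as well as bare integers
#' in the arithmetic range.  Used cell-by-cell by [load_knowledge_base()].
#'
#' @param tokens character vector of cell tokens (whitespace-trimmed; empty
#'   string means no linkage, weight 0).
#' @param entity_kind \code{"DISEASE"} or \code{"BRAIN_ZONE"}.
#' @param where optional character vector parallel to `tokens`, used in error
#'   messages to name the offending cell.
#' @return integer vector of weights.
#' @export
translate_codes <- function(tokens, entity_kind, where = NULL) {
  tokens <- trimws(tokens)
  out <- rep(NA_integer_, length(tokens))
  out[tokens == ""] <- 0L
  valid <- .codes_for_kind(entity_kind)
  is_code <- tokens %in% names(linkage_codes)
  ok_code <- tokens %in% valid
  out[ok_code] <- linkage_codes[tokens[ok_code]]
  is_int <- grepl("^[+-]?[0-9]+$", tokens)
  if (any(is_int)) {
    v <- suppressWarnings(as.integer(tokens[is_int]))
    rng <- .weight_range(entity_kind)
    bad_rng <- v < rng[1] | v > rng[2]
    if (any(bad_rng)) {
      idx <- which(is_int)[bad_rng]
      stop(sprintf("weight %s out of range [%d, %d]%s", tokens[idx[1]],
                   rng[1], rng[2], .at_cell(where, idx[1])))
    }
    out[is_int] <- v
  }
  if (anyNA(out)) {
    idx <- which(is.na(out))[1]
    if (is_code[idx] && !ok_code[idx])
      stop(sprintf("linkage code '%s' is not valid in a %s matrix%s",
                   tokens[idx], entity_kind, .at_cell(where, idx)))
    stop(sprintf("unknown linkage code '%s'%s", tokens[idx],
                 .at_cell(where, idx)))
  }
  out
}

.at_cell <- function(where, i) {
  if (is.null(where)) "" else paste0(" at ", where[i])
}

#' Load a knowledge base from a delimited text file
#'
#' The file layout is a table with symptoms along the rows and entities
#' (diseases or brain zones) across the columns: the first column holds the
#' symptom identifier, the remaining column headers the entity identifiers,
#' and each cell a linkage code (see [linkage_codes]) or a bare integer.
#' Empty cells mean no linkage (weight 0).  An optional second column named
#' \code{group} carries the GENERAL / OCULOMOTOR symptom grouping.  A comment
#' line \code{# entity_kind: DISEASE} (or \code{BRAIN_ZONE}) before the header
#' declares the matrix kind; the \code{entity_kind} argument overrides it.
#'
#' @param source path to a TSV (default) or CSV file, or a connection.
#' @param entity_kind \code{"DISEASE"}, \code{"BRAIN_ZONE"}, or \code{NULL} to
#'   take the kind from the file's \code{# entity_kind:} sidecar line.
#' @param sep field separator, \code{"\t"} or \code{","}; guessed from the
#'   file extension when `source` is a path.
#' @return A validated \code{knowledge_base}.
#' @seealso [write_knowledge_base()] for the exact inverse.
#' @export
load_knowledge_base <- function(source, entity_kind = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (is.character(source) && grepl("\\.csv$", source, TRUE)) "," else "\t"
  lines <- readLines(source, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (is.null(entity_kind)) {
    m <- regmatches(meta, regexpr("entity_kind:\\s*(DISEASE|BRAIN_ZONE)", meta))
    if (!length(m))
      stop("entity_kind not given and no '# entity_kind:' line in file")
    entity_kind <- sub("entity_kind:\\s*", "", m[1])
  }
  entity_kind <- match.arg(entity_kind, c("DISEASE", "BRAIN_ZONE"))
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", strip.white = TRUE)
  if (ncol(tab) < 2L) stop("knowledge-base table needs a symptom column and at least one entity column")
  symptoms <- trimws(tab[[1]])
  groups <- NULL
  ecols <- 2L:ncol(tab)
  if (identical(tolower(names(tab)[2]), "group")) {
    groups <- stats::setNames(toupper(trimws(tab[[2]])), symptoms)
    ecols <- setdiff(ecols, 2L)
    if (length(ecols) == 0L) stop("no entity columns in knowledge-base table")
  }
  entities <- trimws(names(tab)[ecols])
  if (anyDuplicated(symptoms))
    stop("duplicate symptom id: ",
         paste(unique(symptoms[duplicated(symptoms)]), collapse = ", "))
  if (anyDuplicated(entities))
    stop("duplicate entity id: ",
         paste(unique(entities[duplicated(entities)]), collapse = ", "))
  w <- matrix(0L, nrow = length(entities), ncol = length(symptoms),
              dimnames = list(entities, symptoms))
  for (j in seq_along(ecols)) {
    col <- tab[[ecols[j]]]
    where <- sprintf("row '%s', column '%s'", symptoms, entities[j])
    w[j, ] <- translate_codes(col, entity_kind, where)
  }
  knowledge_base(w, entity_kind, symptom_groups = groups)
}

#' Write a knowledge base to delimited text
#'
#' Serializes the weight matrix in the symptom-by-entity layout read by
#' [load_knowledge_base()], emitting the canonical linkage code where one
#' exists for the weight (for disease matrices Y for +1, for zone matrices R)
#' and the bare integer otherwise (e.g. \code{3}, \code{4}).  A sidecar line
#' \code{# entity_kind: ...} is written first, so the file is self-describing.
#' Loading the written file reproduces the knowledge base exactly.
#'
#' @param kb a valid \code{knowledge_base}.
#' @param sink file path or connection.
#' @param sep field separator (tab default).
#' @return `sink`, invisibly.
#' @export
write_knowledge_base <- function(kb, sink, sep = "\t") {
  stopifnot(inherits(kb, "knowledge_base"))
  if (any(grepl(sep, c(kb$symptoms, kb$entities), fixed = TRUE)))
    stop("identifiers contain the field separator; use a different `sep`")
  codes <- .canonical_code_map(kb$entity_kind)
  cell <- function(v) ifelse(as.character(v) %in% names(codes),
                             codes[as.character(v)], as.character(v))
  header <- paste(c("symptom", "group", kb$entities), collapse = sep)
  rows <- vapply(seq_along(kb$symptoms), function(i) {
    paste(c(kb$symptoms[i], kb$symptom_groups[i], cell(kb$weights[, i])),
          collapse = sep)
  }, character(1))
  writeLines(c(paste0("# entity_kind: ", kb$entity_kind), header, rows), sink)
  invisible(sink)
}

.canonical_code_map <- function(entity_kind) {
  if (entity_kind == "DISEASE")
    c(`-3` = "NEV", `-2` = "OTTD", `-1` = "UL", `0` = "N", `1` = "Y",
      `2` = "HR")
  else c(`0` = "N", `1` = "R", `2` = "HR")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base> %s matrix: %d entities x %d symptoms\n",
              x$entity_kind, length(x$entities), length(x$symptoms)))
  cat("entities:", paste(utils::head(x$entities, 6), collapse = ", "),
      if (length(x$entities) > 6) "..." else "", "\n")
  invisible(x)
}
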