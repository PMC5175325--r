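#' Load an item registry
#'
#' Reads an item-registry config (YAML: one block per index, each a list of
#' items with \code{id}, \code{label}, optional \code{aspect} and optional
#' \code{derived$sources}) and validates it against the index cardinalities:
#' 14 infrastructure items, 26 private-market items (exactly one derived),
#' 18 public-quality items. With no argument the registry packaged with
#' pharmRegIRT is loaded, so no authoring is required.
#'
#' @param path path to a registry YAML file, or NULL for the packaged default.
#' @return an \linkS4class{ItemRegistry}.
#' @examples
#' reg <- loadRegistry()
#' nrow(indexItems(reg, "infrastructure"))  # 14
#' @export
loadRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "registry.yaml", package = "pharmRegIRT",
                        mustWork = TRUE)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed registry config: ",
                                           conditionMessage(e), call. = FALSE))
  missingBlocks <- setdiff(.INDEX_NAMES, names(cfg))
  if (length(missingBlocks))
    stop("malformed registry config: missing index block(s) ",
         paste(missingBlocks, collapse = ", "), call. = FALSE)
  rows <- list()
  for (ix in .INDEX_NAMES) {
    block <- cfg[[ix]]
    if (!is.list(block) || is.null(block$items))
      stop("malformed registry config: block '", ix,
           "' must contain an 'items' list", call. = FALSE)
    for (item in block$items) {
      if (is.null(item$id) || is.null(item$label))
        stop("malformed registry config: item without id/label in block '",
             ix, "'", call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        item_id = as.character(item$id),
        label = as.character(item$label),
        index = ix,
        aspect = if (is.null(item$aspect)) NA_character_ else item$aspect,
        derived = !is.null(item$derived),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$sources <- list(
        if (is.null(item$derived)) character()
        else as.character(item$derived$sources))
    }
  }
  items <- do.call(rbind, rows)
  reg <- new("ItemRegistry", items = items)
  validObject(reg)
  reg
}

#' Write an item registry to YAML
#'
#' Inverse of [loadRegistry()]: the written file loads back to an identical
#' registry.
#'
#' @param registry an \linkS4class{ItemRegistry}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRegistry <- function(registry, path) {
  stopifnot(is(registry, "ItemRegistry"))
  out <- list()
  for (ix in .INDEX_NAMES) {
    sub <- registry@items[registry@items$index == ix, ]
    items <- lapply(seq_len(nrow(sub)), function(k) {
      item <- list(id = sub$item_id[k], label = sub$label[k])
      if (!is.na(sub$aspect[k])) item$aspect <- sub$aspect[k]
      if (sub$derived[k]) item$derived <- list(sources = sub$sources[[k]])
      item
    })
    out[[ix]] <- list(items = items)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Items of one index
#'
#' @param registry an \linkS4class{ItemRegistry}.
#' @param index one of \code{"infrastructure"}, \code{"private_market"},
#'   \code{"public_quality"}.
#' @return data.frame of the index's item definitions, in registry order.
#' @export
indexItems <- function(registry, index) {
  stopifnot(is(registry, "ItemRegistry"))
  index <- match.arg(index, .INDEX_NAMES)
  registry@items[registry@items$index == index, , drop = FALSE]
}

#' Default anchor item of an index
#'
#' The item whose discrimination is constrained positive to resolve the
#' reflection invariance of the one-factor model. Defaults are the
#' highest-discrimination item of each index: published GMP requirements
#' (infrastructure), legal control of medicine promotion (private market) and
#' prequalification of products and suppliers (public quality).
#'
#' @inheritParams indexItems
#' @return an item id.
#' @export
defaultAnchor <- function(index) {
  index <- match.arg(index, .INDEX_NAMES)
  c(infrastructure = "5.05.03", private_market = "5.07.01",
    public_quality = "7.10.10.01S")[[index]]
}

#' Code the inspection-regularity composite item
#'
#' The private-market index contains one derived item summarising how often
#' the three market segments (manufacturers, retail distributors, pharmacies
#' and dispensing points of health facilities) are inspected, from the
#' years-between-inspections reported for each segment. Two codings are
#' modeled: \describe{
#'   \item{regular}{1 if all three segments are inspected at least every
#'     three years, or any segment is inspected at least every year.}
#'   \item{annual}{1 if all three segments are inspected at least every
#'     year (strictly harder than \code{regular}).}
#' }
#' A missing frequency for any segment makes the composite missing.
#'
#' @param frequencies numeric vector of length 3, or a 3-column matrix /
#'   data.frame (one row per country): years between inspections per segment,
#'   in the order manufacturers, retail distributors, dispensing points.
#'   Values must be positive; NA marks missing.
#' @param variant \code{"regular"} or \code{"annual"}.
#' @return integer vector of 0/1/NA, one per row.
#' @examples
#' buildInspectionsComposite(c(3, 3, 3), "regular")  # 1
#' buildInspectionsComposite(c(5, 5, 1), "regular")  # 1 (one segment annual)
#' buildInspectionsComposite(c(5, 5, 1), "annual")   # 0
#' @export
buildInspectionsComposite <- function(frequencies,
                                      variant = c("regular", "annual")) {
  variant <- match.arg(variant)
  f <- if (is.null(dim(frequencies))) matrix(as.numeric(frequencies), nrow = 1)
       else as.matrix(frequencies)
  if (ncol(f) != 3L)
    stop("frequencies must have one value per market segment (3)", call. = FALSE)
  storage.mode(f) <- "numeric"
  if (any(f[!is.na(f)] <= 0))
    stop("inspection frequencies must be positive (years between inspections)",
         call. = FALSE)
  anyMissing <- rowSums(is.na(f)) > 0
  out <- if (variant == "regular") {
    as.integer(rowSums(f <= 3) == 3L | rowSums(f <= 1) > 0L)
  } else {
    as.integer(rowSums(f <= 1) == 3L)
  }
  out[anyMissing] <- NA_integer_
  out
}

#' Construct a ResponseSet from a countries-by-items matrix
#'
#' @param responses numeric/integer matrix, countries as rows (rownames =
#'   country ids), items as columns (colnames = item ids); entries 0/1/NA.
#' @param itemData optional data.frame of item metadata (label, aspect, ...)
#'   matching the columns of \code{responses}.
#' @return a validated \linkS4class{ResponseSet}.
#' @export
ResponseSet <- function(responses, itemData = NULL) {
  m <- as.matrix(responses)
  storage.mode(m) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(responses = t(m)),
    rowData = if (is.null(itemData)) NULL else S4Vectors::DataFrame(itemData),
    colData = S4Vectors::DataFrame(row.names = rownames(m)))
  rs <- new("ResponseSet", se)
  validObject(rs)
  rs
}

#' Assemble an analysis-ready response matrix for one index
#'
#' Validates a raw country-by-question survey table against the registry's
#' item set for the given index, computes any derived (composite) items from
#' their source columns, and returns the responses in registry column order.
#' Passing an already-assembled \linkS4class{ResponseSet} (or a table that
#' already contains the derived item's column) returns an equivalent object,
#' so assembly is idempotent.
#'
#' @param raw data.frame with a \code{country} column of ISO-3166 alpha-3
#'   codes and one column per survey question (see [readSurveyCSV()]), or a
#'   \linkS4class{ResponseSet}.
#' @param registry an \linkS4class{ItemRegistry}.
#' @inheritParams indexItems
#' @param variant inspection-regularity coding used for the private-market
#'   composite item.
#' @return a \linkS4class{ResponseSet} with one column per registry item.
#' @export
assembleResponses <- function(raw, registry = loadRegistry(),
                              index = c("infrastructure", "private_market",
                                        "public_quality"),
                              variant = c("regular", "annual")) {
  index <- match.arg(index)
  variant <- match.arg(variant)
  items <- indexItems(registry, index)
  if (is(raw, "ResponseSet")) {
    if (!identical(itemIds(raw), items$item_id))
      stop("ResponseSet items do not match the '", index, "' registry",
           call. = FALSE)
    return(raw)
  }
  raw <- as.data.frame(raw)
  if (!"country" %in% names(raw))
    stop("raw survey table must have a 'country' column", call. = FALSE)
  countries <- as.character(raw$country)
  if (anyDuplicated(countries))
    stop("duplicate country ids: ",
         paste(unique(countries[duplicated(countries)]), collapse = ", "),
         call. = FALSE)
  plain <- items$item_id[!items$derived]
  missingCols <- setdiff(plain, names(raw))
  if (length(missingCols))
    stop("raw survey table lacks item column(s): ",
         paste(missingCols, collapse = ", "), call. = FALSE)

  m <- matrix(NA_integer_, nrow = nrow(raw), ncol = nrow(items),
              dimnames = list(countries, items$item_id))
  for (id in plain) {
    v <- raw[[id]]
    v[v %in% c("", "NA")] <- NA
    v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary value in item '%s' for country '%s'",
                   id, countries[bad[1]]), call. = FALSE)
    m[, id] <- as.integer(v)
  }
  for (k in which(items$derived)) {
    id <- items$item_id[k]
    src <- items$sources[[k]]
    if (all(src %in% names(raw))) {
      f <- as.matrix(raw[, src])
      storage.mode(f) <- "numeric"
      m[, id] <- buildInspectionsComposite(f, variant)
    } else if (id %in% names(raw)) {
      # already-assembled input: accept the precomputed composite column
      v <- suppressWarnings(as.numeric(raw[[id]]))
      bad <- which(!is.na(v) & !(v %in% c(0, 1)))
      if (length(bad))
        stop(sprintf("non-binary value in item '%s' for country '%s'",
                     id, countries[bad[1]]), call. = FALSE)
      m[, id] <- as.integer(v)
    } else {
      stop("derived item '", id, "' needs source column(s) ",
           paste(src, collapse = ", "), " (or a precomputed column)",
           call. = FALSE)
    }
  }
  ResponseSet(m, itemData = data.frame(item_id = items$item_id,
                                       label = items$label,
                                       aspect = items$aspect,
                                       row.names = items$item_id))
}

#' Read / write the survey CSV dialect
#'
#' UTF-8 CSV with a header row of question ids, first column \code{country}
#' (ISO-3166 alpha-3); missing responses encoded as empty cells or "NA".
#'
#' @param path file path.
#' @return \code{readSurveyCSV}: a data.frame suitable for
#'   [assembleResponses()].
#' @export
readSurveyCSV <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
           na.strings = c("", "NA"), fileEncoding = "UTF-8")
}

#' @rdname readSurveyCSV
#' @param x a \linkS4class{ResponseSet}.
#' @export
writeSurveyCSV <- function(x, path) {
  stopifnot(is(x, "ResponseSet"))
  m <- responseMatrix(x)
  df <- data.frame(country = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
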