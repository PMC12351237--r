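#' Split a request string at its modality/reduction key
#'
#' A request may start with a "key" — a prefix naming the modality to
#' pull feature expression from (e.g. `"adt_CD117"`) or the reduction a
#' dimension belongs to (e.g. `"UMAP_1"`) — separated from the remainder
#' by an underscore. Only the first underscore is examined, and only
#' prefixes that match (case-insensitively) a cataloged modality name or
#' reduction name/key count as keys, so feature names that merely
#' contain underscores (`"HLA_DRA"`) pass through untouched.
#'
#' @param var A single non-empty request string.
#' @param catalog A [DataCatalog].
#' @return `list(key=, remainder=)`, or `NULL` when the prefix is not a
#'   known key (absence is a valid result, not an error).
#' @examples
#' cat <- dataCatalog(
#'   modalities = c("rna", "adt"),
#'   features = list(rna = "CD34", adt = "CD117"),
#'   layers = list(rna = "counts", adt = "counts"),
#'   reductions = list(umap = 2),
#'   cellIds = "c1"
#' )
#' splitKey("adt_CD117", cat)
#' splitKey("UMAP_1", cat)
#' splitKey("HLA_DRA", cat)  # NULL: "HLA" is not a key
#' @export
splitKey <- function(var, catalog) {
  stopifnot(is.character(var), length(var) == 1L, nzchar(var))
  pos <- regexpr("_", var, fixed = TRUE)
  if (pos < 0L) return(NULL)
  prefix <- substr(var, 1L, pos - 1L)
  remainder <- substr(var, pos + 1L, nchar(var))
  if (!nzchar(prefix)) return(NULL)
  lp <- tolower(prefix)
  redNames <- names(catalog@reductions)
  redKeys <- vapply(catalog@reductions, function(rd) rd$key, character(1))
  known <- lp %in% tolower(catalog@modalities) ||
    lp %in% tolower(redNames) || lp %in% tolower(redKeys)
  if (!known) return(NULL)
  list(key = prefix, remainder = remainder)
}

# match a key string to a cataloged reduction name (case-insensitive on
# name or key); NA if none
.matchReduction <- function(key, catalog) {
  redNames <- names(catalog@reductions)
  if (!length(redNames)) return(NA_character_)
  redKeys <- vapply(catalog@reductions, function(rd) rd$key, character(1))
  hit <- match(tolower(key), tolower(redNames))
  if (is.na(hit)) hit <- match(tolower(key), tolower(redKeys))
  if (is.na(hit)) NA_character_ else redNames[[hit]]
}

.matchModality <- function(key, catalog) {
  hit <- match(tolower(key), tolower(catalog@modalities))
  if (is.na(hit)) NA_character_ else catalog@modalities[[hit]]
}

.effectiveLayer <- function(catalog, modality, layer) {
  if (is.null(layer)) catalog@defaultLayers[[modality]] else layer
}

.resolvedVar <- function(requested, kind, modality = NA_character_,
                         layer = NA_character_, featureName = NA_character_,
                         reduction = NA_character_, dimIndex = NA_integer_) {
  new("ResolvedVar", requested = requested, kind = kind, modality = modality,
      layer = layer, featureName = featureName, reduction = reduction,
      dimIndex = dimIndex)
}

#' Classify one request string against a catalog
#'
#' Applies the resolution grammar with a fixed precedence:
#' \enumerate{
#'   \item keyed reduction dimension — the key names a reduction and the
#'     remainder is all digits; a digit remainder outside
#'     `1..nDims` is rejected as "dim out of range" rather than
#'     falling through;
#'   \item keyed feature — the key names a modality and the remainder is
#'     (case-sensitively) one of its features;
#'   \item exact metadata column name;
#'   \item bare feature in the default modality;
#'   \item bare feature found only in a non-default modality — rejected
#'     as "ambiguous without modality key" whenever more than one
#'     modality exists (bare lookup beyond the default modality is
#'     honored only for single-modality datasets).
#' }
#' Key matching is case-insensitive; metadata and feature names match
#' exactly. Feature requests carry the effective layer: the explicit
#' `layer` argument if given, else the modality's default layer.
#'
#' @inheritParams splitKey
#' @param layer Optional layer name applied to feature requests.
#' @return A [ResolvedVar], or `list(requested=, reason=)` when the
#'   request cannot be resolved (the batch wrapper [resolveVars()] turns
#'   these into warnings or errors).
#' @export
resolveVar <- function(var, catalog, layer = NULL) {
  sk <- splitKey(var, catalog)
  if (!is.null(sk)) {
    red <- .matchReduction(sk$key, catalog)
    if (!is.na(red) && grepl("^[0-9]+$", sk$remainder)) {
      d <- as.integer(sk$remainder)
      nd <- catalog@reductions[[red]]$nDims
      if (d >= 1L && d <= nd)
        return(.resolvedVar(var, "reduction_dim", reduction = red,
                            dimIndex = d))
      return(list(requested = var,
                  reason = sprintf("dim out of range (reduction '%s' has %d dims)",
                                   red, nd)))
    }
    mod <- .matchModality(sk$key, catalog)
    if (!is.na(mod) && sk$remainder %in% catalog@features[[mod]])
      return(.resolvedVar(var, "feature", modality = mod,
                          layer = .effectiveLayer(catalog, mod, layer),
                          featureName = sk$remainder))
  }
  if (var %in% catalog@metadataColumns)
    return(.resolvedVar(var, "metadata"))
  dm <- catalog@defaultModality
  if (length(dm) == 1L && var %in% catalog@features[[dm]])
    return(.resolvedVar(var, "feature", modality = dm,
                        layer = .effectiveLayer(catalog, dm, layer),
                        featureName = var))
  others <- setdiff(catalog@modalities, dm)
  inOther <- others[vapply(others, function(m)
    var %in% catalog@features[[m]], logical(1))]
  if (length(inOther))
    return(list(requested = var, reason = "ambiguous without modality key"))
  list(requested = var, reason = "not found in catalog")
}

#' Resolve a batch of request strings
#'
#' Applies [resolveVar()] to each element of `vars` in order. Verbatim
#' repeats of an earlier request are set aside (first occurrence wins,
#' keeping column order stable). If every request fails to resolve an
#' error enumerates each with its reason; if only some fail, resolution
#' succeeds and the dropped requests are recorded in the report (and
#' reported as a warning by the fetch functions).
#'
#' @param vars Non-empty character vector of request strings.
#' @inheritParams resolveVar
#' @return A [ResolutionReport].
#' @examples
#' ld <- makeFixture(fixtureSpec(nCells = 10, seed = 1))
#' resolveVars(c("cell_type", "CD34", "UMAP_1"), catalogOf(ld))
#' @export
resolveVars <- function(vars, catalog, layer = NULL) {
  if (!is.character(vars) || !length(vars) || any(!nzchar(vars)))
    stop("vars must be a non-empty character vector of non-empty strings",
         call. = FALSE)
  dedup <- vars[duplicated(vars)]
  firsts <- vars[!duplicated(vars)]
  resolved <- list()
  dropped <- data.frame(requested = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (v in firsts) {
    r <- resolveVar(v, catalog, layer)
    if (is(r, "ResolvedVar")) resolved[[length(resolved) + 1L]] <- r
    else dropped[nrow(dropped) + 1L, ] <- list(r$requested, r$reason)
  }
  if (!length(resolved)) {
    stop(sprintf("none of the requested vars could be resolved: %s",
                 paste(sprintf("'%s' (%s)", dropped$requested, dropped$reason),
                       collapse = "; ")), call. = FALSE)
  }
  new("ResolutionReport", resolved = resolved, dropped = dropped,
      deduplicated = dedup)
}
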