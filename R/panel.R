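# Panel configuration: tubes, marker maps, subset taxonomy, reference
# ranges and ALPS criteria, plus validation of event files against the
# expected panel.

#' Five-level expression scale
#'
#' Ordered names of the per-marker expression levels used throughout the
#' package; level indices run 0 (negative) to 4 (bright).
#' @export
cg_level_names <- c("negative", "dim", "partial", "positive", "bright")

level_index <- function(name) {
  i <- match(name, cg_level_names)
  if (any(is.na(i))) cg_stop("cg_config_error", "unknown expression level '%s'",
                             paste(name[is.na(i)], collapse = ", "))
  i - 1L
}

#' Load and validate a panel configuration
#'
#' Reads the YAML panel schema (tubes with channel/marker maps, subset
#' taxonomy, reference ranges, ALPS flag thresholds) and validates all
#' structural invariants: unique normalized markers per tube, presence of
#' FSC-A/FSC-H/SSC-A, a per-tube taxonomy tree rooted at `"lymphocytes"`
#' with predicates referencing only markers present in the tube, and
#' well-formed reference ranges.
#'
#' @param path path to a YAML panel file, or omit for the bundled default
#'   ALPS panel.
#' @param text YAML text (alternative to `path`).
#' @return a `cg_panel` object.
#' @examples
#' panel <- load_panel()
#' names(panel$tubes)
#' @export
load_panel <- function(path = NULL, text = NULL) {
  if (is.null(path) && is.null(text)) {
    path <- system.file("extdata", "alps_panel.yaml", package = "cytogate")
  }
  raw <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw$tubes))
    cg_stop("cg_config_error", "panel config missing key 'tubes'")

  tubes <- lapply(raw$tubes, parse_tube)
  names(tubes) <- vapply(tubes, `[[`, "", "name")
  if (anyDuplicated(names(tubes)))
    cg_stop("cg_config_error", "duplicate tube names in 'tubes'")

  taxonomy <- parse_taxonomy(raw$taxonomy, tubes)
  ranges <- parse_ranges(raw$reference_ranges, taxonomy)
  criteria <- parse_criteria(raw$alps_criteria)

  panel <- structure(list(
    version = as.character(raw$version %||% "0"),
    tubes = tubes,
    taxonomy = taxonomy,
    reference_ranges = ranges,
    alps_criteria = criteria,
    non_lymphocyte_labels = as.character(unlist(raw$non_lymphocyte_labels))
  ), class = "cg_panel")
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_tube <- function(t) {
  for (key in c("name", "channels", "scatter_channels"))
    if (is.null(t[[key]]))
      cg_stop("cg_config_error", "tube config missing key '%s'", key)
  sc <- t$scatter_channels
  for (key in c("fsc_a", "fsc_h", "ssc_a"))
    if (is.null(sc[[key]]))
      cg_stop("cg_config_error", "tube '%s': scatter_channels missing '%s'",
              t$name, key)
  ch <- do.call(rbind, lapply(t$channels, function(c) {
    if (is.null(c$marker))
      cg_stop("cg_config_error", "tube '%s': channel missing 'marker'", t$name)
    data.frame(detector = as.character(c$detector %||% c$marker),
               fluorochrome = as.character(c$fluorochrome %||% ""),
               marker = as.character(c$marker),
               stringsAsFactors = FALSE)
  }))
  ch$marker_norm <- normalize_marker(ch$marker)
  if (anyDuplicated(ch$marker_norm))
    cg_stop("cg_config_error", "tube '%s': duplicate marker '%s'",
            t$name, ch$marker_norm[duplicated(ch$marker_norm)][1])
  structure(list(
    name = as.character(t$name),
    channels = ch,
    scatter_channels = c(fsc_a = as.character(sc$fsc_a),
                         fsc_h = as.character(sc$fsc_h),
                         ssc_a = as.character(sc$ssc_a)),
    time_channel = if (is.null(t$time_channel)) NA_character_
                   else as.character(t$time_channel)
  ), class = "cg_tube")
}

parse_taxonomy <- function(tax, tubes) {
  if (is.null(tax)) cg_stop("cg_config_error", "panel config missing 'taxonomy'")
  nodes <- lapply(tax, function(n) {
    for (key in c("name", "tube"))
      if (is.null(n[[key]]))
        cg_stop("cg_config_error", "taxonomy node missing key '%s'", key)
    list(name = as.character(n$name),
         parent = if (is.null(n$parent)) NA_character_ else as.character(n$parent),
         tube = as.character(n$tube),
         secondary = isTRUE(n$secondary),
         predicates = lapply(n$predicates, function(p) {
           if (is.null(p$marker) || (is.null(p$min) && is.null(p$max)))
             cg_stop("cg_config_error",
                     "taxonomy node '%s': predicate needs 'marker' and 'min' or 'max'",
                     n$name)
           list(marker = normalize_marker(p$marker),
                min = if (is.null(p$min)) 0L else level_index(p$min),
                max = if (is.null(p$max)) 4L else level_index(p$max))
         }))
  })
  for (tb in names(tubes)) {
    sub <- Filter(function(n) n$tube == tb, nodes)
    nm <- vapply(sub, `[[`, "", "name")
    if (anyDuplicated(nm))
      cg_stop("cg_config_error", "tube '%s': duplicate taxonomy node '%s'",
              tb, nm[duplicated(nm)][1])
    roots <- vapply(sub, function(n) is.na(n$parent), TRUE)
    if (sum(roots) != 1 || sub[[which(roots)]]$name != "lymphocytes")
      cg_stop("cg_config_error",
              "tube '%s': taxonomy must have exactly one root named 'lymphocytes'", tb)
    markers <- tubes[[tb]]$channels$marker_norm
    for (n in sub) {
      if (!is.na(n$parent) && !(n$parent %in% nm))
        cg_stop("cg_config_error", "tube '%s': node '%s' has unknown parent '%s'",
                tb, n$name, n$parent)
      for (p in n$predicates)
        if (!(p$marker %in% markers))
          cg_stop("cg_config_error",
                  "tube '%s': subset '%s' references marker '%s' absent from tube",
                  tb, n$name, p$marker)
    }
    # cycle check: every node must reach the root
    for (n in sub) {
      seen <- character(0); cur <- n
      while (!is.na(cur$parent)) {
        if (cur$name %in% seen)
          cg_stop("cg_config_error", "tube '%s': taxonomy cycle at '%s'", tb, cur$name)
        seen <- c(seen, cur$name)
        cur <- sub[[match(cur$parent, nm)]]
      }
    }
  }
  nodes
}

parse_ranges <- function(rr, taxonomy) {
  if (is.null(rr)) return(data.frame())
  out <- do.call(rbind, lapply(rr, function(r) {
    data.frame(subset = as.character(r$subset),
               tube = as.character(r$tube),
               low = if (is.null(r$low)) NA_real_ else as.numeric(r$low),
               high = if (is.null(r$high)) NA_real_ else as.numeric(r$high),
               denominator = as.character(r$denominator),
               stringsAsFactors = FALSE)
  }))
  bad <- !is.na(out$low) & !is.na(out$high) & out$low >= out$high
  if (any(bad))
    cg_stop("cg_config_error", "reference range for '%s': low must be < high",
            out$subset[bad][1])
  vals <- c(out$low, out$high)
  if (any(!is.na(vals) & (vals < 0 | vals > 100)))
    cg_stop("cg_config_error", "reference ranges must be percentages in [0, 100]")
  tax_keys <- vapply(taxonomy, function(n) paste(n$tube, n$name, sep = "\r"), "")
  miss <- !(paste(out$tube, out$subset, sep = "\r") %in% tax_keys)
  if (any(miss))
    cg_stop("cg_config_error", "reference range references unknown subset '%s' (%s)",
            out$subset[miss][1], out$tube[miss][1])
  out
}

parse_criteria <- function(cr) {
  cr <- cr %||% list()
  out <- list(
    dnt_pct_of_lymphs = as.numeric(cr$dnt_pct_of_lymphs %||% 1.5),
    dnt_pct_of_cd3 = as.numeric(cr$dnt_pct_of_cd3 %||% 2.5),
    dnt_subset = as.character(cr$dnt_subset %||% "TCRab+ DNT"),
    t_subset = as.character(cr$t_subset %||% "T cells"),
    tube = as.character(cr$tube %||% "ALPS-T")
  )
  if (out$dnt_pct_of_lymphs <= 0 || out$dnt_pct_of_cd3 <= 0)
    cg_stop("cg_config_error", "ALPS thresholds must be > 0")
  out
}

#' Serialize a panel configuration to YAML
#'
#' Inverse of [load_panel()]: `load_panel(text = serialize_panel(p))` equals
#' `p` field for field.
#'
#' @param panel a `cg_panel`.
#' @param path optional file to write; when `NULL` the YAML text is returned.
#' @return YAML text (invisibly when written to `path`).
#' @export
serialize_panel <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "cg_panel"))
  lv <- function(i) cg_level_names[i + 1L]
  doc <- list(
    version = panel$version,
    tubes = lapply(unname(panel$tubes), function(t) list(
      name = t$name,
      scatter_channels = as.list(t$scatter_channels),
      time_channel = if (is.na(t$time_channel)) NULL else t$time_channel,
      channels = lapply(seq_len(nrow(t$channels)), function(i) list(
        detector = t$channels$detector[i],
        fluorochrome = t$channels$fluorochrome[i],
        marker = t$channels$marker[i]
      ))
    )),
    taxonomy = lapply(panel$taxonomy, function(n) {
      out <- list(name = n$name,
                  parent = if (is.na(n$parent)) NULL else n$parent,
                  tube = n$tube)
      if (n$secondary) out$secondary <- TRUE
      if (length(n$predicates))
        out$predicates <- lapply(n$predicates, function(p)
          list(marker = p$marker, min = lv(p$min), max = lv(p$max)))
      out
    }),
    non_lymphocyte_labels = as.list(panel$non_lymphocyte_labels),
    reference_ranges = if (nrow(panel$reference_ranges)) {
      lapply(seq_len(nrow(panel$reference_ranges)), function(i) {
        r <- panel$reference_ranges[i, ]
        list(subset = r$subset, tube = r$tube,
             low = if (is.na(r$low)) NULL else r$low,
             high = if (is.na(r$high)) NULL else r$high,
             denominator = r$denominator)
      })
    } else list(),
    alps_criteria = panel$alps_criteria
  )
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Match a sample to the tube it was stained for
#'
#' Compares the sample's stain names against each tube's marker set using
#' normalized marker identity, so the match is insensitive to channel order,
#' case, punctuation and fluorochrome scheme.  On success the sample's
#' channel-to-marker map and tube name are filled in.
#'
#' @param sample a `cg_sample` (see [read_fcs()]).
#' @param panel a `cg_panel`.
#' @return the sample with `$tube` and `$marker_map` set.
#' @export
match_tube <- function(sample, panel) {
  stopifnot(inherits(sample, "cg_sample"), inherits(panel, "cg_panel"))
  ch <- sample$channels
  fluor <- !.is_scatter_or_time(ch$name) & nzchar(ch$stain)
  stains <- normalize_marker(ch$stain[fluor])
  hits <- vapply(panel$tubes, function(t) setequal(stains, t$channels$marker_norm), TRUE)
  if (sum(hits) == 0)
    cg_stop("cg_tube_error",
            "sample stains [%s] match no tube in the panel",
            paste(stains, collapse = ", "))
  if (sum(hits) > 1)
    cg_stop("cg_tube_error", "sample stains match several tubes: %s",
            paste(names(panel$tubes)[hits], collapse = ", "))
  tube <- panel$tubes[[which(hits)]]
  map <- ch$name[fluor]
  names(map) <- stains
  sample$tube <- tube$name
  sample$marker_map <- map[tube$channels$marker_norm]
  names(sample$marker_map) <- tube$channels$marker_norm
  sample
}

# --- taxonomy helpers (internal) -------------------------------------------

tube_taxonomy <- function(panel, tube) {
  Filter(function(n) n$tube == tube, panel$taxonomy)
}

tax_children <- function(nodes, parent, primary_only = TRUE) {
  Filter(function(n) identical(n$parent, parent) &&
           (!primary_only || !n$secondary), nodes)
}

#' Lineage labels for a tube
#'
#' The classifier vocabulary for a tube: children of the lymphocyte root in
#' that tube's taxonomy, plus the configured non-lymphocyte labels
#' (e.g. `"Monocytes"`).
#' @param panel a `cg_panel`.
#' @param tube tube name.
#' @return character vector of labels.
#' @export
lineage_labels <- function(panel, tube) {
  nodes <- tube_taxonomy(panel, tube)
  lin <- vapply(tax_children(nodes, "lymphocytes", primary_only = TRUE),
                `[[`, "", "name")
  c(lin, panel$non_lymphocyte_labels)
}
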