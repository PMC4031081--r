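# Edge-table columns serialized to disk; `NA` encodes not-applicable
# (for example directionality of a lag-0 relation).
edge_table_columns <- c("source", "target", "lag_tau", "sign", "mean_assoc",
                        "q_relation", "p_directionality", "q_treatment",
                        "treatment_flag", "robust", "directed")

#' Read and validate a long-form cohort table
#'
#' Expects a CSV (or TSV, chosen by file extension) with columns
#' `subject_id, hormone, occasion, time_min, value`. Each (subject,
#' hormone, occasion) series must sit on a complete uniform grid with
#' spacing `expected_delta`; duplicate keys and gaps are rejected with a
#' message naming the offender.
#'
#' @param path input file.
#' @param expected_delta grid spacing in minutes.
#' @return A validated data frame.
#' @export
read_cohort <- function(path, expected_delta = 10) {
  df <- if (grepl("\\.tsv$", path, ignore.case = TRUE))
    read.delim(path, stringsAsFactors = FALSE)
  else read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df, expected_delta)
}

validate_cohort <- function(df, expected_delta = 10) {
  check_cohort_columns(df)
  key <- paste(df$subject_id, df$hormone, df$occasion, df$time_min,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L)
    stop(sprintf("duplicate (subject, hormone, occasion, time) key at row %d: %s / %s / %s / t=%s",
                 dup[1], df$subject_id[dup[1]], df$hormone[dup[1]],
                 df$occasion[dup[1]], df$time_min[dup[1]]), call. = FALSE)
  if (anyNA(df$value) || any(!is.finite(df$value)))
    stop("cohort values must be finite", call. = FALSE)
  sk <- paste(df$subject_id, df$hormone, df$occasion, sep = "\r")
  for (g in split(df$time_min, sk)) {
    tt <- sort(g)
    if (length(tt) > 1L && max(abs(diff(tt) - expected_delta)) > 1e-8) {
      id <- strsplit(names(which(vapply(split(df$time_min, sk), function(x)
        isTRUE(all.equal(sort(x), tt)), logical(1)))[1]), "\r")[[1]]
      stop(sprintf("non-uniform or gapped time grid for %s / %s / %s (expected spacing %g min)",
                   id[1], id[2], id[3], expected_delta), call. = FALSE)
    }
  }
  df
}

#' @rdname read_cohort
#' @param df cohort data frame to write.
#' @export
write_cohort <- function(df, path) {
  check_cohort_columns(df)
  write.csv(df[, required_cohort_columns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read and write dynamic-network edge tables
#'
#' Tab-separated tables with columns `source, target, lag_tau, sign,
#' mean_assoc, q_relation, p_directionality, q_treatment, treatment_flag,
#' robust, directed`. `NA` encodes not-applicable values - in particular
#' the directionality p-value of lag-0 relations, which have no
#' direction by definition. The round trip is lossless, and an identical
#' analysis (same configuration and seed) rewrites a byte-identical
#' file.
#'
#' @param edges edge table (rows of a `dynamic_network` table).
#' @param path file path.
#' @return `read_edge_table()` returns the validated data frame;
#'   `write_edge_table()` returns `path` invisibly.
#' @export
write_edge_table <- function(edges, path) {
  for (col in setdiff(edge_table_columns, names(edges)))
    edges[[col]] <- NA
  out <- edges[, edge_table_columns, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(source = "character",
                                  target = "character",
                                  sign = "character",
                                  treatment_flag = "character"))
  missing <- setdiff(edge_table_columns, names(df))
  if (length(missing) > 0L)
    stop(sprintf("edge table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad_sign <- setdiff(unique(df$sign), c("+", "-"))
  if (length(bad_sign) > 0L)
    stop(sprintf("unknown sign value '%s'", bad_sign[1]), call. = FALSE)
  bad_flag <- setdiff(unique(df$treatment_flag[!is.na(df$treatment_flag)]),
                      c("significant", "tendency", "none"))
  if (length(bad_flag) > 0L)
    stop(sprintf("unknown treatment_flag value '%s'", bad_flag[1]),
         call. = FALSE)
  df$lag_tau <- as.integer(df$lag_tau)
  df$robust <- as.logical(df$robust)
  df$directed <- as.logical(df$directed)
  df
}

#' Bundle a network with node annotation and provenance
#'
#' @param edges edge table (dynamic-network rows).
#' @param tier optional named character vector mapping hormone names to a
#'   tier annotation (for example `"pituitary"` vs `"peripheral"`).
#' @param config the [analysis_config()] used (hashed into provenance).
#' @param seed the seed used (recorded in provenance).
#' @return A list of class `network_document` with `nodes`, `edges` and
#'   `provenance` (config hash, seed, creation timestamp).
#' @export
network_document <- function(edges, tier = NULL, config = NULL,
                             seed = NA_integer_) {
  hormones <- sort(unique(c(edges$source, edges$target)))
  tiers <- if (is.null(tier)) rep(NA_character_, length(hormones))
    else unname(tier[hormones])
  nodes <- data.frame(name = hormones, tier = tiers,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 provenance = list(
                   config_hash = rlang::hash(unclass(config)),
                   seed = seed,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
            class = "network_document")
}

#' Export and import a network as GraphML
#'
#' Nodes carry a `tier` attribute; edges carry `sign` (`+`/`-`, negative
#' relations are conventionally rendered dashed), `lag_tau`, `directed`,
#' `treatment_flag` (a marker for relations changed by the intervention)
#' and `q_relation`. Directed relations are emitted as directed GraphML
#' edges, undirected ones as undirected. The files load in standard
#' graph libraries, and `read_graphml()` restores all attributes.
#'
#' @param doc a [network_document()].
#' @param path output file.
#' @return `export_graphml()` returns `path` invisibly; `read_graphml()`
#'   returns a `network_document`.
#' @export
export_graphml <- function(doc, path) {
  root <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    list(id = "d_tier", dom = "node", name = "tier", type = "string"),
    list(id = "d_sign", dom = "edge", name = "sign", type = "string"),
    list(id = "d_lag", dom = "edge", name = "lag_tau", type = "int"),
    list(id = "d_dir", dom = "edge", name = "directed", type = "boolean"),
    list(id = "d_flag", dom = "edge", name = "treatment_flag",
         type = "string"),
    list(id = "d_q", dom = "edge", name = "q_relation", type = "double"),
    list(id = "d_hash", dom = "graph", name = "config_hash",
         type = "string"),
    list(id = "d_seed", dom = "graph", name = "seed", type = "string"),
    list(id = "d_created", dom = "graph", name = "created",
         type = "string"))
  for (k in keys)
    xml2::xml_add_child(root, "key", id = k$id, `for` = k$dom,
                        attr.name = k$name, attr.type = k$type)
  graph <- xml2::xml_add_child(root, "graph", id = "hormone_network",
                               edgedefault = "undirected")
  prov <- doc$provenance
  add_data <- function(node, key, value) {
    if (is.na(value)) return(invisible(NULL))
    d <- xml2::xml_add_child(node, "data", key = key)
    xml2::xml_text(d) <- as.character(value)
  }
  add_data(graph, "d_hash", prov$config_hash %||% NA)
  add_data(graph, "d_seed", prov$seed %||% NA)
  add_data(graph, "d_created", prov$created %||% NA)
  for (i in seq_len(nrow(doc$nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = doc$nodes$name[i])
    add_data(nd, "d_tier", doc$nodes$tier[i])
  }
  ed <- doc$edges
  for (i in seq_len(nrow(ed))) {
    directed <- isTRUE(ed$directed[i])
    e <- xml2::xml_add_child(graph, "edge", source = ed$source[i],
                             target = ed$target[i],
                             directed = if (directed) "true" else "false")
    add_data(e, "d_sign", ed$sign[i])
    add_data(e, "d_lag", ed$lag_tau[i])
    add_data(e, "d_dir", if (directed) "true" else "false")
    add_data(e, "d_flag", ed$treatment_flag[i])
    add_data(e, "d_q", format(ed$q_relation[i], digits = 17))
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' @rdname export_graphml
#' @export
read_graphml <- function(path) {
  x <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(x), d1 = "g")
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node,
      sprintf("./g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  graph <- xml2::xml_find_first(x, ".//g:graph", ns)
  node_els <- xml2::xml_find_all(graph, "./g:node", ns)
  nodes <- data.frame(
    name = xml2::xml_attr(node_els, "id"),
    tier = vapply(node_els, get_data, character(1), key = "d_tier"),
    stringsAsFactors = FALSE)
  edge_els <- xml2::xml_find_all(graph, "./g:edge", ns)
  edges <- data.frame(
    source = xml2::xml_attr(edge_els, "source"),
    target = xml2::xml_attr(edge_els, "target"),
    lag_tau = as.integer(vapply(edge_els, get_data, character(1),
                                key = "d_lag")),
    sign = vapply(edge_els, get_data, character(1), key = "d_sign"),
    q_relation = as.numeric(vapply(edge_els, get_data, character(1),
                                   key = "d_q")),
    treatment_flag = vapply(edge_els, get_data, character(1),
                            key = "d_flag"),
    directed = vapply(edge_els, get_data, character(1),
                      key = "d_dir") == "true",
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 provenance = list(config_hash = get_data(graph, "d_hash"),
                                   seed = get_data(graph, "d_seed"),
                                   created = get_data(graph, "d_created"))),
            class = "network_document")
}

#' Write per-series deconvolution diagnostics as JSON
#'
#' @param series_list list of secretion series from [deconvolve()].
#' @param path output JSON file.
#' @export
write_diagnostics <- function(series_list, path) {
  diag <- lapply(series_list, function(s) {
    c(list(subject_id = s$subject_id, hormone = s$hormone,
           occasion = s$occasion), s$diagnostics)
  })
  jsonlite::write_json(diag, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
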