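# File formats: .abc whitespace edge lists, .idx cluster index files,
# TSV expression matrices, PDB alpha-carbon extraction, TSV result tables.
# Fields split on runs of spaces/tabs; lines starting with "#" are skipped.

read_text_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- which(nzchar(trimmed) & !startsWith(trimmed, "#"))
  list(lineno = keep, tokens = strsplit(trimmed[keep], "[ \t]+"))
}

#' Read a whitespace-separated edge list (.abc)
#'
#' Each non-blank, non-comment line holds two node labels and an optional
#' numeric weight, separated by runs of spaces or tabs. Nodes enter the
#' network in first-seen order; duplicate edges (either orientation) are
#' merged and self-loops dropped with a warning.
#'
#' @param path path to the `.abc` file
#' @return a [network()] object
#' @export
read_abc <- function(path) {
  rec <- read_text_records(path)
  nf <- lengths(rec$tokens)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad))
    stop(sprintf("line %d: expected 2 or 3 whitespace-separated fields, got %d",
                 rec$lineno[bad[1]], nf[bad[1]]))
  from <- vapply(rec$tokens, `[`, character(1), 1)
  to <- vapply(rec$tokens, `[`, character(1), 2)
  w <- rep(NA_real_, length(nf))
  has3 <- nf == 3
  if (any(has3)) {
    wtxt <- vapply(rec$tokens[has3], `[`, character(1), 3)
    wval <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wval)) {
      first <- which(is.na(wval))[1]
      stop(sprintf("line %d: third field '%s' is not numeric",
                   rec$lineno[has3][first], wtxt[first]))
    }
    w[has3] <- wval
  }
  network(cbind(from, to), weights = if (any(has3)) w else NULL)
}

#' Write a network as a .abc edge list
#'
#' Isolated nodes cannot be represented in the format and trigger a
#' warning. Weighted edges get a third column; weights are printed with
#' enough digits to round-trip exactly through [read_abc()].
#'
#' @param net a `carto_network`
#' @param path output path
#' @param comment optional string written first as a `#` comment line
#' @return `path`, invisibly
#' @export
write_abc <- function(net, path, comment = NULL) {
  if (n_nodes(net)) {
    iso <- names(which(degrees(net) == 0))
    if (length(iso))
      warning("isolated node(s) not representable in .abc format: ",
              paste(utils::head(iso, 5), collapse = ", "))
  }
  lines <- character()
  if (n_edges(net)) {
    lines <- paste(net$edges[, 1], net$edges[, 2])
    if (!is.null(net$weights)) {
      hasw <- !is.na(net$weights)
      lines[hasw] <- paste(lines[hasw],
                           format(net$weights[hasw], digits = 17, trim = TRUE))
    }
  }
  if (!is.null(comment)) lines <- c(paste0("# ", comment), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a cluster index file (.idx)
#'
#' Two whitespace-separated columns: node label, cluster label. Cluster
#' labels are opaque strings; first-seen order defines the internal module
#' indices. A node listed twice with conflicting clusters is an error.
#'
#' @param path path to the `.idx` file
#' @return a [partition()] object
#' @export
read_idx <- function(path) {
  rec <- read_text_records(path)
  nf <- lengths(rec$tokens)
  bad <- which(nf != 2)
  if (length(bad))
    stop(sprintf("line %d: expected 2 whitespace-separated fields, got %d",
                 rec$lineno[bad[1]], nf[bad[1]]))
  node <- vapply(rec$tokens, `[`, character(1), 1)
  cl <- vapply(rec$tokens, `[`, character(1), 2)
  first <- cl[match(node, node)]
  conflict <- which(cl != first)
  if (length(conflict))
    stop(sprintf("line %d: node '%s' reassigned from cluster '%s' to '%s'",
                 rec$lineno[conflict[1]], node[conflict[1]],
                 first[conflict[1]], cl[conflict[1]]))
  keep <- !duplicated(node)
  partition(setNames(cl[keep], node[keep]))
}

#' Write a partition as a .idx file
#'
#' Module labels are written verbatim, so the file round-trips through
#' [read_idx()] to an identical assignment.
#'
#' @param p a `carto_partition`
#' @param path output path
#' @param comment optional string written first as a `#` comment line
#' @return `path`, invisibly
#' @export
write_idx <- function(p, path, comment = NULL) {
  lines <- if (length(p$nodes)) paste(p$nodes, p$labels) else character()
  if (!is.null(comment)) lines <- c(paste0("# ", comment), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Construct an expression matrix
#'
#' @param values numeric matrix, genes in rows, samples in columns
#' @param genes,samples row / column labels; default to the dimnames
#' @return object of class `expression_matrix` with fields `genes`,
#'   `samples`, `values`
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              samples = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(genes) || is.null(samples))
    stop("gene and sample labels are required")
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (anyDuplicated(genes))
    stop("duplicate gene ID: ", genes[duplicated(genes)][1])
  if (length(genes) != nrow(values) || length(samples) != ncol(values))
    stop("label lengths do not match the value matrix")
  dimnames(values) <- list(genes, samples)
  structure(list(genes = genes, samples = samples, values = values),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression matrix: %d genes x %d samples, %d missing>\n",
              length(x$genes), length(x$samples), sum(is.na(x$values))))
  invisible(x)
}

#' Read a gene x sample expression table (TSV)
#'
#' First row: sample names (with or without a leading cell for the gene
#' column); first column: gene IDs. Cells `NA` or empty are recorded as
#' missing, never as zero.
#'
#' @param path path to the tab-separated table
#' @return an [expression_matrix()]
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty expression table")
  toks <- strsplit(lines, "\t", fixed = TRUE)
  header <- toks[[1]]
  body <- toks[-1]
  if (length(body)) {
    nf <- lengths(body)
    ragged <- which(nf != nf[1])
    if (length(ragged))
      stop(sprintf("line %d: ragged row (%d fields, expected %d)",
                   ragged[1] + 1, nf[ragged[1]], nf[1]))
    samples <- if (length(header) == nf[1]) header[-1] else header
    if (length(samples) != nf[1] - 1)
      stop("header does not match the number of data columns")
  } else {
    samples <- header[-1]
  }
  genes <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(genes))
    stop("duplicate gene ID: ", genes[duplicated(genes)][1])
  vals <- matrix(NA_real_, length(genes), length(samples))
  for (r in seq_along(body)) {
    cells <- body[[r]][-1]
    v <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(v) & !(cells %in% c("NA", "", "NaN")))
    if (length(bad))
      stop(sprintf("line %d: non-numeric value '%s'", r + 1, cells[bad[1]]))
    vals[r, ] <- v
  }
  expression_matrix(vals, genes, samples)
}

#' Extract alpha-carbon coordinates from a PDB file
#'
#' Keeps one CA atom per residue from ATOM records (HETATM excluded);
#' when alternate locations are present the first encountered wins.
#' Residue labels are `chain:resSeq` with any insertion code appended,
#' which keeps them unique within a chain.
#'
#' @param path path to a PDB-format file
#' @param chains optional character vector restricting to these chain IDs
#' @return data frame with columns `label`, `x`, `y`, `z` (Angstrom), one
#'   row per residue in file order
#' @export
read_pdb_ca <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  sel <- at$type == "ATOM" & at$elety == "CA"
  if (!is.null(chains)) sel <- sel & at$chain %in% chains
  at <- at[sel, , drop = FALSE]
  if (!nrow(at)) stop("no alpha carbons")
  ins <- at$insert
  ins[is.na(ins)] <- ""
  key <- paste(at$chain, at$resno, ins)
  keep <- !duplicated(key)
  at <- at[keep, , drop = FALSE]
  ins <- ins[keep]
  data.frame(label = paste0(at$chain, ":", at$resno, ins),
             x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a node attribute table (TSV)
#'
#' Tab-separated with a header row; the first column holds node labels and
#' every other column becomes a string-valued attribute.
#'
#' @param path path to the attribute TSV
#' @return data frame with a `node` column plus one column per attribute
#' @export
read_node_attributes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "node"
  if (anyDuplicated(df$node))
    stop("duplicate node label in attributes: ",
         df$node[duplicated(df$node)][1])
  df
}

fmt6 <- function(x) {
  out <- vapply(signif(x, 6), function(v) format(v, trim = TRUE),
                character(1))
  out[is.na(x)] <- "NA"
  out
}

#' Write the cartography result table (TSV)
#'
#' Columns: node, module, degree, kappa, z, P, region, then one column per
#' node attribute in attribute-name sorted order. Floats are printed with
#' 6 significant digits so tables diff cleanly across runs.
#'
#' @param records data frame from [build_cartography()]
#' @param path output path
#' @param attrs optional attribute table as returned by
#'   [read_node_attributes()]; nodes missing from it get empty cells
#' @param comment optional string written first as a `#` comment line
#' @return `path`, invisibly
#' @export
write_node_table <- function(records, path, attrs = NULL, comment = NULL) {
  stopifnot(is.data.frame(records))
  tab <- data.frame(node = records$node, module = records$module,
                    degree = records$degree, kappa = records$kappa,
                    z = fmt6(records$z), P = fmt6(records$P),
                    region = records$region,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(attrs)) {
    acols <- sort(setdiff(names(attrs), "node"))
    m <- match(tab$node, attrs$node)
    for (a in acols) {
      v <- as.character(attrs[[a]])[m]
      v[is.na(v)] <- ""
      tab[[a]] <- v
    }
  }
  lines <- c(paste(names(tab), collapse = "\t"),
             do.call(paste, c(unname(tab), sep = "\t")))
  if (!is.null(comment)) lines <- c(paste0("# ", comment), lines)
  writeLines(lines, path)
  invisible(path)
}
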