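#' Read a membrane-protein gene table (XML or tissue-TSV dialect)
#'
#' Parses an HPA-style export of the predicted-membrane-protein class into
#' two tables: a gene record table and a long normal-tissue expression
#' profile. Two dialects are supported:
#'
#' * `xml`: entries carry an Ensembl-style identifier, a display name, their
#'   protein-class memberships and (optionally) a tissue-expression block of
#'   per-tissue, per-cell-type ordinal levels. A gene without a
#'   tissue-expression block has no protein-level (IHC) evidence. Elements
#'   outside this reduced dialect are ignored.
#' * `tsv`: the normal-tissue table dialect with columns `Gene`, `Gene name`,
#'   `Tissue`, `Cell type`, `Level` (and optionally `Reliability`, parsed but
#'   unused). A single row with blank `Tissue` and `Level` marks a gene
#'   listed without IHC evidence. All genes in this dialect belong to the
#'   membrane class.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"xml"`, `"tsv"`. `"auto"` decides by file
#'   extension.
#' @return A list with components:
#'   \describe{
#'     \item{genes}{data.frame with `gene_id`, `gene_symbol`, `is_membrane`,
#'       `has_protein_evidence`.}
#'     \item{normal}{data.frame with `gene_id`, `tissue`, `cell_type`,
#'       `level` (canonical level names), one row per annotated cell type.}
#'   }
#' @export
read_membrane_gene_table <- function(path, format = c("auto", "xml", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "tsv"
  }
  out <- if (format == "xml") {
    read_gene_table_xml(path)
  } else {
    read_gene_table_tsv(path)
  }
  if (anyDuplicated(out$genes$gene_id)) {
    dup <- unique(out$genes$gene_id[duplicated(out$genes$gene_id)])
    stop("duplicate gene_id in gene table: ",
         paste(sQuote(dup), collapse = ", "), call. = FALSE)
  }
  out
}

read_gene_table_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot read XML gene table ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  entries <- xml2::xml_find_all(doc, ".//entry")
  genes <- vector("list", length(entries))
  normal <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    entry <- entries[[i]]
    id_node <- xml2::xml_find_first(entry, "./identifier")
    gene_id <- xml2::xml_attr(id_node, "id")
    if (is.na(gene_id) || !nzchar(gene_id)) {
      stop("entry ", i, " has no identifier id attribute", call. = FALSE)
    }
    gene_symbol <- xml2::xml_text(xml2::xml_find_first(entry, "./name"))
    classes <- xml2::xml_attr(
      xml2::xml_find_all(entry, "./proteinClasses/proteinClass"), "name"
    )
    is_membrane <- any(tolower(classes) == "predicted membrane proteins")
    cells <- xml2::xml_find_all(entry, "./tissueExpression/data/tissueCell")
    has_evidence <- length(cells) > 0
    genes[[i]] <- data.frame(
      gene_id = gene_id,
      gene_symbol = if (is.na(gene_symbol)) gene_id else gene_symbol,
      is_membrane = is_membrane,
      has_protein_evidence = has_evidence,
      stringsAsFactors = FALSE
    )
    if (has_evidence) {
      tissue <- xml2::xml_text(xml2::xml_find_first(cells, "../tissue"))
      cell_type <- xml2::xml_text(xml2::xml_find_first(cells, "./cellType"))
      level <- parse_ihc_level(
        xml2::xml_text(xml2::xml_find_first(cells, "./level")),
        context = gene_id
      )
      normal[[i]] <- data.frame(
        gene_id = gene_id, tissue = tissue, cell_type = cell_type,
        level = level, stringsAsFactors = FALSE
      )
    }
  }
  list(
    genes = rbind_or_empty(genes, gene_table_proto()),
    normal = rbind_or_empty(normal, normal_table_proto())
  )
}

read_gene_table_tsv <- function(path) {
  tab <- read_tsv_checked(path, c("Gene", "Gene name", "Tissue",
                                  "Cell type", "Level"))
  tissue <- trimws(tab[["Tissue"]])
  level <- trimws(tab[["Level"]])
  blank <- !nzchar(tissue) & !nzchar(level)
  ids <- unique(tab[["Gene"]])
  has_ev <- vapply(ids, function(g) {
    any(tab[["Gene"]] == g & !blank)
  }, logical(1))
  sym <- tab[["Gene name"]][match(ids, tab[["Gene"]])]
  genes <- data.frame(
    gene_id = ids, gene_symbol = sym,
    is_membrane = TRUE, has_protein_evidence = unname(has_ev),
    stringsAsFactors = FALSE
  )
  keep <- !blank
  normal <- data.frame(
    gene_id = tab[["Gene"]][keep],
    tissue = tissue[keep],
    cell_type = trimws(tab[["Cell type"]][keep]),
    level = if (any(keep)) {
      parse_ihc_level(level[keep], context = path)
    } else character(0),
    stringsAsFactors = FALSE
  )
  list(genes = genes, normal = normal)
}

#' Read a pathology patient-count table
#'
#' Tab-separated table with columns `Gene`, `Gene name`, `Cancer`, `High`,
#' `Medium`, `Low`, `Not detected` holding non-negative integer patient
#' counts per (gene, tumor type). Blank count cells denote unassayed
#' categories and are read as 0; a row whose four counts total 0 is carried
#' but yields an undefined quasi H-score downstream.
#'
#' @param path Path to the TSV file.
#' @return data.frame with `gene_id`, `gene_symbol`, `tumor_type`, `n_high`,
#'   `n_medium`, `n_low`, `n_not_detected`.
#' @export
read_pathology_counts <- function(path) {
  tab <- read_tsv_checked(path, c("Gene", "Gene name", "Cancer", "High",
                                  "Medium", "Low", "Not detected"))
  parse_count <- function(col) {
    raw <- trimws(as.character(tab[[col]]))
    raw[!nzchar(raw)] <- "0"
    n <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(n) | n != floor(n))
    if (length(bad) > 0) {
      stop("malformed ", sQuote(col), " count in ", path, " at data row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    neg <- which(n < 0)
    if (length(neg) > 0) {
      stop("negative ", sQuote(col), " count in ", path, " at data row(s) ",
           paste(neg, collapse = ", "), call. = FALSE)
    }
    as.integer(n)
  }
  data.frame(
    gene_id = tab[["Gene"]],
    gene_symbol = tab[["Gene name"]],
    tumor_type = tab[["Cancer"]],
    n_high = parse_count("High"),
    n_medium = parse_count("Medium"),
    n_low = parse_count("Low"),
    n_not_detected = parse_count("Not detected"),
    stringsAsFactors = FALSE
  )
}

#' Read a predicted-surfaceome membership table
#'
#' Delimited table with at least one identifier column (`Gene`, `GeneName`
#' or `UniProt`); extra columns are ignored. When the table is keyed by
#' gene symbol (`GeneName`) and an id map is supplied, symbols are resolved
#' to gene ids; unresolved rows are dropped with a message.
#'
#' @param path Path to the delimited file (tab or comma separated).
#' @param id_map Optional data.frame with `gene_id` and `gene_symbol`
#'   columns used to resolve symbol-keyed tables.
#' @return Character vector of unique member gene identifiers.
#' @export
read_surfaceome <- function(path, id_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  id_cols <- intersect(c("Gene", "GeneName", "UniProt"), names(tab))
  if (length(id_cols) == 0) {
    stop("surfaceome table ", path,
         " has no identifier column (Gene, GeneName or UniProt)",
         call. = FALSE)
  }
  col <- id_cols[[1]]
  ids <- trimws(as.character(tab[[col]]))
  ids <- ids[nzchar(ids)]
  if (col == "GeneName" && !is.null(id_map)) {
    resolved <- id_map$gene_id[match(ids, id_map$gene_symbol)]
    dropped <- ids[is.na(resolved)]
    if (length(dropped) > 0) {
      message("read_surfaceome: dropping ", length(dropped),
              " unresolved symbol(s): ",
              paste(utils::head(unique(dropped), 5), collapse = ", "))
    }
    ids <- resolved[!is.na(resolved)]
  }
  unique(ids)
}

#' Read a per-(gene, tumor type) FPKM table
#'
#' Tab-separated table with columns `Gene`, `Cancer`, `FPKM`. Missing
#' (gene, tumor) pairs are simply absent (never imputed as zero); negative
#' FPKM values are rejected.
#'
#' @param path Path to the TSV file.
#' @return data.frame with `gene_id`, `tumor_type`, `fpkm`.
#' @export
read_fpkm <- function(path) {
  tab <- read_tsv_checked(path, c("Gene", "Cancer", "FPKM"))
  fpkm <- suppressWarnings(as.numeric(tab[["FPKM"]]))
  bad <- which(is.na(fpkm))
  if (length(bad) > 0) {
    stop("malformed FPKM value in ", path, " at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(fpkm < 0)) {
    stop("negative FPKM value in ", path, " at data row(s) ",
         paste(which(fpkm < 0), collapse = ", "), call. = FALSE)
  }
  data.frame(
    gene_id = tab[["Gene"]],
    tumor_type = tab[["Cancer"]],
    fpkm = fpkm,
    stringsAsFactors = FALSE
  )
}

# ---- writers (the exact dialects the readers accept) -----------------------

level_token <- function(level) {
  c(not_detected = "Not detected", low = "Low", medium = "Medium",
    high = "High")[level]
}

#' Write a membrane-gene table as XML
#'
#' Inverse of the `xml` dialect of [read_membrane_gene_table()].
#'
#' @param genes,normal Tables as returned by [read_membrane_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table_xml <- function(genes, normal, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<proteinAtlas>")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(
      lines, "  <entry>",
      sprintf("    <name>%s</name>", esc(g$gene_symbol)),
      sprintf("    <identifier id=\"%s\" db=\"Ensembl\"/>", esc(g$gene_id)),
      "    <proteinClasses>",
      if (g$is_membrane) {
        "      <proteinClass name=\"Predicted membrane proteins\"/>"
      } else {
        "      <proteinClass name=\"Other class\"/>"
      },
      "    </proteinClasses>"
    )
    prof <- normal[normal$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(prof) > 0) {
      lines <- c(lines, "    <tissueExpression>")
      for (tis in unique(prof$tissue)) {
        sub <- prof[prof$tissue == tis, , drop = FALSE]
        lines <- c(
          lines, "      <data>",
          sprintf("        <tissue>%s</tissue>", esc(tis)),
          sprintf(paste0("        <tissueCell><cellType>%s</cellType>",
                         "<level type=\"expression\">%s</level></tissueCell>"),
                  esc(sub$cell_type), level_token(sub$level)),
          "      </data>"
        )
      }
      lines <- c(lines, "    </tissueExpression>")
    }
    lines <- c(lines, "  </entry>")
  }
  lines <- c(lines, "</proteinAtlas>")
  writeLines(lines, path)
  invisible(path)
}

#' Write a membrane-gene table in the tissue-TSV dialect
#'
#' Inverse of the `tsv` dialect of [read_membrane_gene_table()]; genes
#' without protein evidence are written as one blank-tissue placeholder row.
#'
#' @inheritParams write_gene_table_xml
#' @return `path`, invisibly.
#' @export
write_gene_table_tsv <- function(genes, normal, path) {
  sym <- genes$gene_symbol[match(normal$gene_id, genes$gene_id)]
  rows <- data.frame(
    Gene = normal$gene_id, `Gene name` = sym, Tissue = normal$tissue,
    `Cell type` = normal$cell_type, Level = level_token(normal$level),
    Reliability = "Approved", check.names = FALSE, stringsAsFactors = FALSE
  )
  no_ev <- genes[!genes$has_protein_evidence, , drop = FALSE]
  if (nrow(no_ev) > 0) {
    rows <- rbind(rows, data.frame(
      Gene = no_ev$gene_id, `Gene name` = no_ev$gene_symbol, Tissue = "",
      `Cell type` = "", Level = "", Reliability = "",
      check.names = FALSE, stringsAsFactors = FALSE
    ))
  }
  rows <- rows[order(match(rows$Gene, genes$gene_id)), , drop = FALSE]
  write_tsv(rows, path)
}

#' Write a pathology patient-count table
#'
#' Inverse of [read_pathology_counts()].
#'
#' @param pathology Table as returned by [read_pathology_counts()].
#' @param path Output path.
#' @param gene_symbols Optional named vector mapping gene_id to symbol; used
#'   when `pathology` lacks a `gene_symbol` column.
#' @return `path`, invisibly.
#' @export
write_pathology_tsv <- function(pathology, path, gene_symbols = NULL) {
  sym <- if ("gene_symbol" %in% names(pathology)) {
    pathology$gene_symbol
  } else {
    unname(gene_symbols[pathology$gene_id])
  }
  write_tsv(data.frame(
    Gene = pathology$gene_id, `Gene name` = sym,
    Cancer = pathology$tumor_type, High = pathology$n_high,
    Medium = pathology$n_medium, Low = pathology$n_low,
    `Not detected` = pathology$n_not_detected,
    check.names = FALSE, stringsAsFactors = FALSE
  ), path)
}

#' Write a surfaceome membership table
#'
#' Inverse of [read_surfaceome()] for id-keyed tables.
#'
#' @param members Character vector of member gene ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surfaceome_tsv <- function(members, path) {
  write_tsv(data.frame(Gene = unique(members), stringsAsFactors = FALSE),
            path)
}

#' Write an FPKM table
#'
#' Inverse of [read_fpkm()].
#'
#' @param fpkm Table as returned by [read_fpkm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_tsv <- function(fpkm, path) {
  write_tsv(data.frame(
    Gene = fpkm$gene_id, Cancer = fpkm$tumor_type, FPKM = fpkm$fpkm,
    check.names = FALSE, stringsAsFactors = FALSE
  ), path)
}

# ---- internals -------------------------------------------------------------

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  missing <- setdiff(required_cols, names(tab))
  if (length(missing) > 0) {
    stop("table ", path, " lacks required column(s): ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  tab
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

rbind_or_empty <- function(pieces, proto) {
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0) return(proto)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

gene_table_proto <- function() {
  data.frame(gene_id = character(0), gene_symbol = character(0),
             is_membrane = logical(0), has_protein_evidence = logical(0),
             stringsAsFactors = FALSE)
}

normal_table_proto <- function() {
  data.frame(gene_id = character(0), tissue = character(0),
             cell_type = character(0), level = character(0),
             stringsAsFactors = FALSE)
}
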