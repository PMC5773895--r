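# Plain-text model archive: a header of tab-separated key/value lines,
# then named array blocks ("@array name nrow ncol" followed by rows with
# 17 significant digits, so round trips are exact). Forest ensembles hold
# opaque tree state and are archived with R's native serialization
# instead, behind the same read/write surface.

#' @keywords internal
.write_array <- function(con, name, x) {
  x <- as.matrix(x)
  writeLines(sprintf("@array\t%s\t%d\t%d", name, nrow(x), ncol(x)), con)
  writeLines(vapply(seq_len(nrow(x)), function(i) {
    paste(sprintf("%.17g", x[i, ]), collapse = "\t")
  }, character(1)), con)
}

#' @keywords internal
.write_ids <- function(con, name, ids) {
  writeLines(sprintf("@ids\t%s\t%d", name, length(ids)), con)
  writeLines(ids, con)
}

#' Serialize a fitted model to disk
#'
#' `mlp_sae`/`stacked_regressor` and `lasso_fit` models are written as a
#' flat plain-text archive (header of key-value metadata: dimensions,
#' activations, dropout retention, configuration echo; then one block per
#' weight/bias array and identifier list). `forest_fit` models are written
#' with [saveRDS()]. [read_model()] restores any of them.
#'
#' @param model A fitted `mlp_sae`, `stacked_regressor`, `lasso_fit`, or
#'   `forest_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "forest_fit")) {
    saveRDS(model, path)
    return(invisible(path))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  kv <- function(k, v) writeLines(paste0("#", k, "\t", paste(v, collapse = "\t")), con)
  if (inherits(model, "stacked_regressor")) {
    kv("model_kind", if (inherits(model, "mlp_sae")) "mlp_sae" else "stacked_regressor")
    kv("input_dim", model$input_dim)
    kv("n_genes", model$n_genes)
    kv("n_hidden", length(model$hidden))
    kv("activations", vapply(model$hidden, function(l) l$activation$name, character(1)))
    p <- .drop_p(model)
    kv("dropout_p_hidden", sprintf("%.17g", p$p_hidden))
    kv("dropout_p_input", sprintf("%.17g", p$p_input))
    if (!is.null(model$config)) {
      for (k in names(model$config)) {
        kv(paste0("config.", k), format(model$config[[k]], digits = 17))
      }
    }
    if (!is.null(model$marker_ids)) .write_ids(con, "marker_ids", model$marker_ids)
    if (!is.null(model$gene_ids)) .write_ids(con, "gene_ids", model$gene_ids)
    for (l in seq_along(model$hidden)) {
      .write_array(con, paste0("hidden_W_", l), model$hidden[[l]]$W)
      .write_array(con, paste0("hidden_b_", l), model$hidden[[l]]$b)
    }
    .write_array(con, "output_W", model$output_W)
    .write_array(con, "output_b", model$output_b)
  } else if (inherits(model, "lasso_fit")) {
    kv("model_kind", "lasso")
    kv("alpha", sprintf("%.17g", model$alpha))
    if (!is.null(model$marker_ids)) .write_ids(con, "marker_ids", model$marker_ids)
    if (!is.null(model$gene_ids)) .write_ids(con, "gene_ids", model$gene_ids)
    .write_array(con, "w", model$w)
    .write_array(con, "intercepts", model$intercepts)
  } else {
    stop("write_model: unsupported model class: ", paste(class(model), collapse = "/"))
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(first, "#model_kind")) {
    return(readRDS(path))  # forest archive
  }
  lines <- readLines(path, warn = FALSE)
  meta <- list(); arrays <- list(); ids <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#")) {
      parts <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1L]]
      meta[[parts[1L]]] <- parts[-1L]
      i <- i + 1L
    } else if (startsWith(ln, "@array")) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      nr <- as.integer(parts[3L]); nc <- as.integer(parts[4L])
      block <- lines[i + seq_len(nr)]
      vals <- as.numeric(unlist(strsplit(block, "\t", fixed = TRUE)))
      arrays[[parts[2L]]] <- matrix(vals, nr, nc, byrow = TRUE)
      i <- i + 1L + nr
    } else if (startsWith(ln, "@ids")) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      n <- as.integer(parts[3L])
      ids[[parts[2L]]] <- lines[i + seq_len(n)]
      i <- i + 1L + n
    } else {
      i <- i + 1L
    }
  }
  kind <- meta$model_kind
  if (kind %in% c("mlp_sae", "stacked_regressor")) {
    L <- as.integer(meta$n_hidden)
    hidden <- lapply(seq_len(L), function(l) list(
      W = arrays[[paste0("hidden_W_", l)]],
      b = drop(arrays[[paste0("hidden_b_", l)]]),
      activation = activation(meta$activations[l])
    ))
    p_h <- as.numeric(meta$dropout_p_hidden)
    p_i <- as.numeric(meta$dropout_p_input)
    model <- structure(list(
      hidden = hidden,
      output_W = arrays$output_W,
      output_b = drop(arrays$output_b),
      input_dim = as.integer(meta$input_dim),
      n_genes = as.integer(meta$n_genes),
      dropout = if (p_h < 1 || p_i < 1) dropout_spec(p_h, p_i) else NULL,
      marker_ids = ids$marker_ids,
      gene_ids = ids$gene_ids
    ), class = "stacked_regressor")
    cfg_keys <- grep("^config\\.", names(meta), value = TRUE)
    if (length(cfg_keys)) {
      model$config <- stats::setNames(lapply(meta[cfg_keys], identity),
                                      sub("^config\\.", "", cfg_keys))
    }
    model
  } else if (kind == "lasso") {
    structure(list(
      w = structure(arrays$w, dimnames = list(ids$marker_ids, ids$gene_ids)),
      intercepts = drop(arrays$intercepts),
      alpha = as.numeric(meta$alpha),
      marker_ids = ids$marker_ids,
      gene_ids = ids$gene_ids
    ), class = "lasso_fit")
  } else {
    stop("read_model: unknown model kind '", kind, "'")
  }
}
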