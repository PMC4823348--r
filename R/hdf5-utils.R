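# Internal HDF5 plumbing.  Everything here is path-based: each helper opens
# the file, does its work and closes every handle, so rhdf5 calls and the
# compiled dimension-scale/vlen helpers can be interleaved freely.

.h5_ro <- "H5F_ACC_RDONLY"

# does `path` (all intermediate links included) exist in `file`?
.h5exists <- function(file, path) {
  comps <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1L]]
  fid <- rhdf5::H5Fopen(file, flags = .h5_ro)
  on.exit(rhdf5::H5Fclose(fid))
  cur <- ""
  for (c in comps) {
    cur <- paste0(cur, "/", c)
    if (!rhdf5::H5Lexists(fid, cur)) return(FALSE)
  }
  TRUE
}

# "group", "dataset" or NA
.h5kind <- function(file, path) {
  if (!.h5exists(file, path)) return(NA_character_)
  fid <- rhdf5::H5Fopen(file, flags = .h5_ro)
  on.exit(rhdf5::H5Fclose(fid))
  oid <- rhdf5::H5Oopen(fid, path)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
  typ <- rhdf5::H5Iget_type(oid)
  if (identical(typ, "H5I_GROUP")) "group"
  else if (identical(typ, "H5I_DATASET")) "dataset"
  else NA_character_
}

# create all missing groups along `path`
.h5ensure_group <- function(file, path) {
  comps <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1L]]
  cur <- ""
  for (c in comps) {
    cur <- paste0(cur, "/", c)
    if (!.h5exists(file, cur)) rhdf5::h5createGroup(file, cur)
  }
  invisible(cur)
}

# names of the immediate children of a group ("" if absent)
.h5children <- function(file, group) {
  if (!.h5exists(file, group)) return(character())
  fid <- rhdf5::H5Fopen(file, flags = .h5_ro)
  on.exit(rhdf5::H5Fclose(fid))
  gid <- rhdf5::H5Gopen(fid, group)
  on.exit(rhdf5::H5Gclose(gid), add = TRUE, after = FALSE)
  info <- rhdf5::h5ls(gid, recursive = FALSE)
  if (is.null(info) || !nrow(info)) character() else info$name
}

# attributes of a node as a plain list (string/numeric only; the reference
# bookkeeping of dimension scales is skipped), rhdf5 markers dropped
.h5attrs <- function(file, path) {
  a <- .Call(C_attrs, file, path)
  a[!grepl("^rhdf5-", names(a))]
}

.h5write_attr <- function(file, path, name, value) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid))
  oid <- rhdf5::H5Oopen(fid, path)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
  # fixed-length strings: stored inline in the object header, whereas
  # variable-length attribute strings cost a global-heap collection each
  rhdf5::h5writeAttribute(value, oid, name, variableLengthString = FALSE,
                          asScalar = length(value) == 1L)
  invisible(NULL)
}

.h5delete_attr <- function(file, path, name) {
  rhdf5::h5deleteAttribute(file, path, name)
  invisible(NULL)
}

# full paths of every dataset in the file (optionally below `under`)
.h5datasets <- function(file, under = "/") {
  info <- rhdf5::h5ls(file, datasetinfo = FALSE)
  if (!nrow(info)) return(character())
  full <- file.path(sub("/$", "", info$group), info$name)
  full <- gsub("//", "/", full, fixed = TRUE)
  keep <- info$otype == "H5I_DATASET"
  if (under != "/")
    keep <- keep & startsWith(full, paste0(sub("/$", "", under), "/"))
  full[keep]
}

## wrappers over the compiled helpers ---------------------------------------

.ds_set_scale <- function(file, dset, name)
  .Call(C_ds_set_scale, file, dset, name)

.ds_attach <- function(file, dset, scale, dim, label)
  .Call(C_ds_attach, file, dset, scale, as.integer(dim), label)

.ds_scales <- function(file, dset, dim)
  .Call(C_ds_scales, file, dset, as.integer(dim))

.ds_label <- function(file, dset, dim)
  .Call(C_ds_label, file, dset, as.integer(dim))

.vlen_write <- function(file, path, rows)
  .Call(C_vlen_write, file, path, lapply(rows, as.numeric))

.vlen_write_row <- function(file, path, i, values)
  .Call(C_vlen_write_row, file, path, as.integer(i), as.numeric(values))

.vlen_read <- function(file, path) .Call(C_vlen_read, file, path)

.dtype_class <- function(file, path) .Call(C_dtype_class, file, path)

# dataset extents in file (row-major) order
.dset_dims <- function(file, path) .Call(C_dset_dims, file, path)

## dataset creation ---------------------------------------------------------

# Create a 2D double dataset with file-order extent (P, Q): P sources on
# file dimension 0, Q samples on dimension 1.  rhdf5 maps R dimension order
# reversed onto the file, so R-side dims are (Q, P).  Chunked storage is
# used when the dataset must be extendible (append) or compressed;
# otherwise the layout is contiguous.
.create_matrix_dataset <- function(file, path, P, Q, compression = "none",
                                   level = 6L, extendible = FALSE,
                                   fillValue = NULL) {
  chunked <- extendible || compression == "gzip"
  args <- list(file = file, dataset = path, dims = c(Q, P),
               storage.mode = "double")
  if (chunked) {
    args$maxdims <- c(rhdf5::H5Sunlimited(), P)
    args$chunk <- c(max(1L, min(Q, 1024L)), max(1L, min(P, 64L)))
    args$filter <- if (compression == "gzip") "GZIP" else "NONE"
    args$level <- if (compression == "gzip") level else 0L
    # byte-shuffle before deflate: standard for floating-point payloads
    args$shuffle <- compression == "gzip"
    if (!is.null(fillValue)) args$fillValue <- fillValue
  } else {
    args["chunk"] <- list(NULL)      # contiguous layout
    args$filter <- "NONE"
    args$level <- 0L
  }
  do.call(rhdf5::h5createDataset, args)
  invisible(path)
}

# write a P x Q R matrix into a dataset with file-order extent (P, Q)
.write_matrix <- function(file, path, mat, colOffset = 0L) {
  Q <- ncol(mat)
  if (!Q) return(invisible(NULL))
  rhdf5::h5write(t(mat), file, path,
                 index = list(colOffset + seq_len(Q), seq_len(nrow(mat))))
  invisible(NULL)
}

# read a dataset with file extent (P, Q) back as a P x Q R matrix
.read_matrix <- function(file, path, cols = NULL) {
  d <- .dset_dims(file, path)
  P <- d[1L]
  if (is.null(cols)) cols <- seq_len(d[2L])
  if (!length(cols) || P == 0L)
    return(matrix(numeric(), nrow = P, ncol = length(cols)))
  m <- rhdf5::h5read(file, path, index = list(cols, NULL))
  if (is.null(dim(m))) dim(m) <- c(length(cols), P)
  t(m)
}

# create + write a 1D double dataset (file extent = length(x))
.write_vector_dataset <- function(file, path, x, compression = "none",
                                  level = 6L, extendible = FALSE) {
  n <- length(x)
  chunked <- (extendible || compression == "gzip") && n > 0L
  args <- list(file = file, dataset = path, dims = n,
               storage.mode = "double")
  if (chunked) {
    args$maxdims <- rhdf5::H5Sunlimited()
    args$chunk <- max(1L, min(n, 1024L))
    args$filter <- if (compression == "gzip") "GZIP" else "NONE"
    args$level <- if (compression == "gzip") level else 0L
    args$shuffle <- compression == "gzip"
  } else {
    args["chunk"] <- list(NULL)      # contiguous layout
    args$filter <- "NONE"
    args$level <- 0L
  }
  do.call(rhdf5::h5createDataset, args)
  if (n) rhdf5::h5write(as.numeric(x), file, path, index = list(seq_len(n)))
  invisible(path)
}

# append to a 1D double dataset, returning the new length
.append_vector_dataset <- function(file, path, x) {
  n0 <- .dset_dims(file, path)[1L]
  k <- length(x)
  if (!k) return(invisible(n0))
  rhdf5::h5set_extent(file, path, n0 + k)
  rhdf5::h5write(as.numeric(x), file, path, index = list(n0 + seq_len(k)))
  invisible(n0 + k)
}

.write_string_dataset <- function(file, path, x) {
  if (.h5exists(file, path)) rhdf5::h5delete(file, path)
  rhdf5::h5write(as.character(x), file, path)
  invisible(path)
}
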