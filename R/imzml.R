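#' @keywords internal
#' Minimal imzML 1.1 support: an XML index file (mzML dialect) paired with
#' a binary .ibd file whose first 16 bytes repeat the UUID declared in the
#' XML. Both continuous mode (one shared m/z axis) and processed mode
#' (per-spectrum m/z arrays) are handled; values are 64-bit little-endian
#' floats. Integrity on read is enforced by UUID agreement and declared
#' byte extents (no SHA-1 is computed).
NULL

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

random_uuid_bytes <- function() {
  as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
}

uuid_to_string <- function(bytes) {
  hx <- format(bytes)
  paste0(paste(hx[1:4], collapse = ""), "-", paste(hx[5:6], collapse = ""),
         "-", paste(hx[7:8], collapse = ""), "-",
         paste(hx[9:10], collapse = ""), "-",
         paste(hx[11:16], collapse = ""))
}

#' Write a spectral image cube as imzML
#'
#' @param cube an [msi_cube].
#' @param path output path (`.imzML` extension optional); the paired `.ibd`
#'   is written next to it.
#' @param mode `"continuous"` (shared m/z axis, default) or `"processed"`
#'   (m/z axis repeated per spectrum).
#' @param skip_black drop all-zero pixels from the file (they are
#'   reconstructed as black pixels on read).
#' @return the `.imzML` path, invisibly.
#' @export
write_imzml <- function(cube, path, mode = c("continuous", "processed"),
                        skip_black = FALSE) {
  mode <- match.arg(mode)
  h <- cube_height(cube); w <- cube_width(cube); k <- cube_nvar(cube)
  flat <- matrix(cube$values, nrow = h * w, ncol = k)
  lin <- seq_len(h * w)
  if (skip_black) lin <- lin[rowSums(flat[lin, , drop = FALSE]) > 0]
  coords <- cbind(x = ((lin - 1L) %/% h) + 1L,  # x = col
                  y = ((lin - 1L) %% h) + 1L)   # y = row
  imzml_write_raw(path, mz = cube$variables,
                  intensities = lapply(lin, function(i) flat[i, ]),
                  coords = coords, grid = c(h, w), mode = mode,
                  pixel_size = cube$pixel_size)
}

# low-level writer: explicit m/z axis (list for processed mode), spectra and
# 1-based (x, y) coordinates
imzml_write_raw <- function(path, mz, intensities, coords, grid,
                            mode = "continuous", pixel_size = 10) {
  p <- imzml_paths(path)
  uuid <- random_uuid_bytes()
  con <- file(p$ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  n <- length(intensities)
  mz_list <- if (is.list(mz)) mz else rep(list(mz), if (mode == "processed") n else 1)
  recs <- vector("list", n)
  mz_offset <- NA; mz_len <- NA
  if (mode == "continuous") {
    mz_offset <- offset; mz_len <- length(mz_list[[1]])
    writeBin(as.numeric(mz_list[[1]]), con, size = 8, endian = "little")
    offset <- offset + 8 * mz_len
  }
  for (i in seq_len(n)) {
    if (mode == "processed") {
      mzi <- mz_list[[i]]
      mz_offset <- offset; mz_len <- length(mzi)
      writeBin(as.numeric(mzi), con, size = 8, endian = "little")
      offset <- offset + 8 * mz_len
    }
    ii <- as.numeric(intensities[[i]])
    recs[[i]] <- list(x = coords[i, 1], y = coords[i, 2],
                      mz_offset = mz_offset, mz_len = mz_len,
                      int_offset = offset, int_len = length(ii))
    writeBin(ii, con, size = 8, endian = "little")
    offset <- offset + 8 * length(ii)
  }
  spectra_xml <- vapply(seq_len(n), function(i) {
    r <- recs[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, r$int_len, r$x, r$y,
      r$mz_offset, r$mz_len, 8L * r$mz_len,
      r$int_offset, r$int_len, 8L * r$int_len)
  }, character(1))
  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  mode_name <- paste(mode, "mode")
  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<fileDescription><fileContent>\n',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
            uuid_to_string(uuid)),
    sprintf('<cvParam cvRef="IMS" accession="%s" name="%s"/>\n',
            mode_acc, mode_name),
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">\n',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '</referenceableParamGroup>\n',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '</referenceableParamGroup>\n',
    '</referenceableParamGroupList>\n',
    '<scanSettingsList count="1"><scanSettings id="scan1">\n',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
            grid[2]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
            grid[1]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%g"/>\n',
            pixel_size),
    '</scanSettings></scanSettingsList>\n',
    sprintf('<run id="run1"><spectrumList count="%d">\n', n),
    paste(spectra_xml, collapse = "\n"),
    '\n</spectrumList></run></mzML>\n')
  writeLines(xml, p$xml)
  invisible(p$xml)
}

xp <- function(node, path) xml2::xml_find_all(node, path)

cv_value <- function(node, accession) {
  v <- xml2::xml_attr(
    xp(node, sprintf(".//cvParam[@accession='%s']", accession)), "value")
  if (length(v) == 0) NA_character_ else v[[1]]
}

#' Read an imzML dataset into a spectral image cube
#'
#' Supports continuous and processed mode. The pixel grid is inferred from
#' the scan-settings extents (falling back to the coordinate maxima);
#' coordinates absent from the file become all-zero (black) pixels, so
#' non-rectangular acquisitions are padded, never rejected. An unsorted m/z
#' axis is re-sorted ascending with intensities permuted consistently; in
#' processed mode spectra are aligned onto the union m/z axis.
#'
#' @param path path to the `.imzML` file (paired `.ibd` expected next to
#'   it).
#' @param modality modality tag for the resulting cube.
#' @return an [msi_cube].
#' @export
read_imzml <- function(path, modality = "lipid_neg") {
  p <- imzml_paths(path)
  if (!file.exists(p$xml)) stop("imzML file not found: ", p$xml)
  if (!file.exists(p$ibd)) stop("ibd file not found: ", p$ibd)
  doc <- xml2::read_xml(p$xml)
  # namespace-prefixed absolute queries: document-order single scans are
  # orders of magnitude faster than per-spectrum or local-name() XPath
  ns <- xml2::xml_ns(doc)
  pfx <- if (length(ns) && any(names(ns) == "d1")) "d1:" else ""
  q_all <- function(path) xml2::xml_find_all(doc, path, ns = ns)
  cv_all <- function(accession)
    xml2::xml_attr(q_all(sprintf("//%scvParam[@accession='%s']",
                                 pfx, accession)), "value")
  cv_one <- function(accession) {
    v <- cv_all(accession)
    if (length(v) == 0) NA_character_ else v[[1]]
  }
  uuid_decl <- cv_one("IMS:1000080")
  ibd_size <- file.info(p$ibd)$size
  con <- file(p$ibd, "rb")
  on.exit(close(con), add = TRUE)
  uuid_ibd <- readBin(con, "raw", 16)
  if (!is.na(uuid_decl)) {
    decl <- tolower(gsub("[{}-]", "", uuid_decl))
    if (!identical(decl, paste(format(uuid_ibd), collapse = "")))
      stop("corrupt imzML: ibd UUID does not match the declared identifier")
  }
  n <- length(q_all(sprintf("//%sspectrum", pfx)))
  if (n == 0) stop("imzML contains no spectra")
  xs <- as.integer(cv_all("IMS:1000050"))
  ys <- as.integer(cv_all("IMS:1000051"))
  refs <- xml2::xml_attr(
    q_all(sprintf("//%sreferenceableParamGroupRef", pfx)), "ref")
  offs <- as.numeric(cv_all("IMS:1000102"))
  lens <- as.integer(cv_all("IMS:1000103"))
  if (length(xs) != n || length(ys) != n || length(refs) != 2 * n ||
      length(offs) != 2 * n || length(lens) != 2 * n)
    stop("corrupt imzML: inconsistent spectrum metadata")
  read_array <- function(offset, len) {
    if (offset + 8 * len > ibd_size)
      stop("corrupt imzML: binary array extends past end of ibd file")
    seek(con, where = offset, origin = "start")
    readBin(con, "numeric", n = len, size = 8, endian = "little")
  }
  mzs <- vector("list", n); ints <- vector("list", n)
  mz_cache_off <- -1; mz_cache <- NULL   # continuous mode: one shared axis
  for (i in seq_len(n)) {
    for (a in c(2 * i - 1, 2 * i)) {
      if (identical(refs[a], "mzArray")) {
        if (offs[a] != mz_cache_off) {
          mz_cache <- read_array(offs[a], lens[a])
          mz_cache_off <- offs[a]
        }
        mzs[[i]] <- mz_cache
      } else {
        ints[[i]] <- read_array(offs[a], lens[a])
      }
    }
    if (length(mzs[[i]]) != length(ints[[i]]))
      stop("corrupt imzML: m/z and intensity array lengths differ")
  }
  w <- suppressWarnings(as.integer(cv_one("IMS:1000042")))
  h <- suppressWarnings(as.integer(cv_one("IMS:1000043")))
  if (is.na(w)) w <- max(xs)
  if (is.na(h)) h <- max(ys)
  w <- max(w, xs); h <- max(h, ys)   # pad to coordinate extents
  px <- suppressWarnings(as.numeric(cv_one("IMS:1000046")))
  if (is.na(px)) px <- 10
  shared_axis <- n == 1 || all(vapply(mzs[-1], identical, logical(1),
                                      y = mzs[[1]]))
  axis <- if (shared_axis) sort(mzs[[1]]) else sort(unique(unlist(mzs)))
  k <- length(axis)
  flat <- matrix(0, h * w, k)
  lin <- (xs - 1L) * h + ys
  if (shared_axis) {
    idx <- match(mzs[[1]], axis)
    m <- do.call(rbind, ints)
    flat[lin, idx] <- m
  } else {
    for (i in seq_len(n)) {
      idx <- match(mzs[[i]], axis)
      flat[lin[i], idx] <- ints[[i]]
    }
  }
  vals <- array(flat, dim = c(h, w, k))
  msi_cube(vals, axis, pixel_size = px, modality = modality)
}
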