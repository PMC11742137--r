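# Minimal xlsx writer: one numeric grid per sheet, no styles, stored (un-
# compressed) zip entries, own CRC-32.  Exists because the environment has an
# xlsx *reader* (readxl) but no writer; output is deliberately the smallest
# document readxl and other readers accept.  NA cells are written as absent
# cells (the empty-field convention for missing data).

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L)) {
        bitwXor(-306674912L, bitwShiftR(bitwAnd(cc, -2L), 1))
      } else {
        bitwShiftR(bitwAnd(cc, -2L), 1)
      }
    }
    tab[i + 1] <- cc
  }
  tab
})

crc32 <- function(raw_bytes) {
  cc <- -1L
  for (b in as.integer(raw_bytes)) {
    cc <- bitwXor(crc32_table[bitwAnd(bitwXor(cc, b), 255L) + 1L],
                  bitwShiftR(bitwAnd(cc, -256L), 8))
  }
  bitwXor(cc, -1L)
}

le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
le32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# `files`: named list of raw vectors
zip_store <- function(files, out) {
  con <- file(out, "wb"); on.exit(close(con))
  centrals <- list(); off <- 0L
  for (nm in names(files)) {
    data <- files[[nm]]
    crc <- crc32(data); n <- length(data); name <- charToRaw(nm)
    hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), le16(20), le16(0), le16(0),
             le16(0), le16(0), le32(crc), le32(n), le32(n),
             le16(length(name)), le16(0))
    writeBin(c(hdr, name, data), con)
    centrals[[nm]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), le16(20), le16(20),
                        le16(0), le16(0), le16(0), le16(0), le32(crc), le32(n),
                        le32(n), le16(length(name)), le16(0), le16(0), le16(0),
                        le16(0), le32(0), le32(off), name)
    off <- off + length(hdr) + length(name) + n
  }
  cd <- do.call(c, unname(centrals))
  writeBin(cd, con)
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), le16(0), le16(0),
             le16(length(files)), le16(length(files)),
             le32(length(cd)), le32(off), le16(0)), con)
  invisible(out)
}

excel_col <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

sheet_xml <- function(m) {
  col_names <- vapply(seq_len(ncol(m)), excel_col, "")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    present <- which(!is.na(m[i, ]))
    cells <- sprintf('<c r="%s%d"><v>%.17g</v></c>', col_names[present], i, m[i, present])
    sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
  }, "")
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

write_xlsx_grid <- function(m, path, sheet = "Sheet1") {
  ct <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/></Types>')
  rels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/></Relationships>')
  wb <- sprintf(paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="%s" sheetId="1" r:id="rId1"/></sheets></workbook>'), sheet)
  wbrels <- paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/></Relationships>')
  zip_store(list("[Content_Types].xml" = charToRaw(ct),
                 "_rels/.rels" = charToRaw(rels),
                 "xl/workbook.xml" = charToRaw(wb),
                 "xl/_rels/workbook.xml.rels" = charToRaw(wbrels),
                 "xl/worksheets/sheet1.xml" = charToRaw(sheet_xml(m))),
            path)
}
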