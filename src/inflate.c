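/* Bounded zlib inflate for mzML/imzML binary arrays.
 *
 * memDecompress() grows its output buffer without bound when handed a
 * truncated RFC-1950 stream; spectra from damaged files must instead fail
 * with a clean, catchable error.  This wrapper inflates with a hard output
 * cap and maps zlib return codes to R errors.
 */
#include <string.h>
#include <R.h>
#include <Rinternals.h>
#include <zlib.h>

SEXP msio_inflate(SEXP data, SEXP cap_)
{
    const R_xlen_t n = XLENGTH(data);
    const double cap_d = REAL(cap_)[0];
    const size_t cap = (size_t) cap_d;

    if (n == 0)
        return allocVector(RAWSXP, 0);

    size_t alloc = (size_t) n * 4 + 64;
    if (alloc > cap) alloc = cap;
    unsigned char *out = (unsigned char *) R_alloc(alloc, 1);

    z_stream strm;
    memset(&strm, 0, sizeof strm);
    if (inflateInit(&strm) != Z_OK)
        error("zlib: inflateInit failed");

    strm.next_in = RAW(data);
    strm.avail_in = (uInt) n;
    size_t have = 0;
    int ret;

    for (;;) {
        strm.next_out = out + have;
        strm.avail_out = (uInt) (alloc - have);
        ret = inflate(&strm, Z_NO_FLUSH);
        have = alloc - strm.avail_out;

        if (ret == Z_STREAM_END)
            break;

        if (ret == Z_OK || ret == Z_BUF_ERROR) {
            if (strm.avail_out > 0) {
                /* output space left but no progress possible: input ran dry */
                inflateEnd(&strm);
                error("zlib: truncated stream (%lu bytes consumed)",
                      (unsigned long) ((size_t) n - strm.avail_in));
            }
            if (alloc >= cap) {
                inflateEnd(&strm);
                error("zlib: inflated size exceeds cap of %lu bytes",
                      (unsigned long) cap);
            }
            size_t na = alloc * 2;
            if (na > cap) na = cap;
            unsigned char *no = (unsigned char *) R_alloc(na, 1);
            memcpy(no, out, have);
            out = no;
            alloc = na;
            continue;
        }

        inflateEnd(&strm);
        error("zlib: inflate failed (%s)",
              strm.msg ? strm.msg : "corrupt stream");
    }

    inflateEnd(&strm);
    SEXP res = PROTECT(allocVector(RAWSXP, (R_xlen_t) have));
    memcpy(RAW(res), out, have);
    UNPROTECT(1);
    return res;
}
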