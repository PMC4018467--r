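// Adaptive Lempel-Ziv (LZW) coder in the dialect of the classic Unix
// `compress` utility: .Z container (magic 0x1F 0x9D), block mode, code
// widths growing 9..16 bits, CLEAR code 256 with dictionary reset driven
// by a compression-ratio checkpoint every 10000 input bytes.
//
// Two quirks of the historical coder matter for interoperability with the
// reference decoder (gzip/uncompress) and are reproduced here:
//  * the code stream is padded to an n_bits-byte group boundary relative
//    to the start of the current width segment whenever the width changes
//    or a CLEAR is emitted (padding bytes are zeros);
//  * the width check runs after packing each code and before the
//    dictionary insertion for that step.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

namespace {

const int kBits = 16;               // maxbits, as compress -b16 (the default)
const int kClear = 256;             // block-mode dictionary reset code
const int kFirst = 257;             // first free dictionary entry
const long kCheckGap = 10000;       // ratio checkpoint interval (input bytes)

struct BitWriter {
  std::vector<uint8_t> out;
  uint64_t buf = 0;
  int nbuf = 0;                     // bits held in buf
  size_t seg_start = 0;             // byte offset where current width segment began

  void put(uint32_t code, int nbits) {
    buf |= static_cast<uint64_t>(code) << nbuf;
    nbuf += nbits;
    while (nbuf >= 8) {
      out.push_back(static_cast<uint8_t>(buf & 0xFF));
      buf >>= 8;
      nbuf -= 8;
    }
  }
  // flush to a multiple of nbits bytes from seg_start, zero padding
  void pad(int nbits) {
    while (nbuf > 0 || (out.size() - seg_start) % nbits != 0) {
      out.push_back(static_cast<uint8_t>(buf & 0xFF));
      buf >>= 8;
      nbuf = nbuf > 8 ? nbuf - 8 : 0;
    }
    seg_start = out.size();
  }
  void flush() {
    while (nbuf > 0) {
      out.push_back(static_cast<uint8_t>(buf & 0xFF));
      buf >>= 8;
      nbuf = nbuf > 8 ? nbuf - 8 : 0;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".lzw_compress")]]
RawVector lzw_compress_cpp(RawVector input) {
  BitWriter w;
  // header: magic + flags (block mode | maxbits)
  std::vector<uint8_t> header = {0x1F, 0x9D,
                                 static_cast<uint8_t>(kBits | 0x80)};
  const R_xlen_t n = input.size();
  if (n == 0) return RawVector(header.begin(), header.end());

  int n_bits = 9;
  long maxcode = (1L << n_bits) - 1;
  const long maxmax = 1L << kBits;
  long free_ent = kFirst;
  std::unordered_map<uint32_t, long> table;
  table.reserve(1 << 17);
  long ratio = 0;
  long checkpoint = kCheckGap;

  long ent = input[0];
  long in_count = 1;
  for (R_xlen_t i = 1; i < n; ++i) {
    ++in_count;
    const uint32_t c = input[i];
    const uint32_t key = (static_cast<uint32_t>(ent) << 8) | c;
    auto hit = table.find(key);
    if (hit != table.end()) {
      ent = hit->second;
      continue;
    }
    w.put(static_cast<uint32_t>(ent), n_bits);
    if (free_ent > maxcode) {
      w.pad(n_bits);
      ++n_bits;
      maxcode = (n_bits == kBits) ? maxmax : (1L << n_bits) - 1;
    }
    if (free_ent < maxmax) {
      table[key] = free_ent++;
    } else if (in_count >= checkpoint) {
      // block-mode ratio check; reset dictionary if ratio degrades
      checkpoint = in_count + kCheckGap;
      const long bytes_out = 3 + static_cast<long>(w.out.size());
      const long rat = (in_count << 8) / bytes_out;
      if (rat > ratio) {
        ratio = rat;
      } else {
        ratio = 0;
        table.clear();
        free_ent = kFirst;
        w.put(kClear, n_bits);
        w.pad(n_bits);
        n_bits = 9;
        maxcode = (1L << n_bits) - 1;
      }
    }
    ent = c;
  }
  w.put(static_cast<uint32_t>(ent), n_bits);
  w.flush();

  RawVector res(3 + w.out.size());
  std::copy(header.begin(), header.end(), res.begin());
  std::copy(w.out.begin(), w.out.end(), res.begin() + 3);
  return res;
}

// [[Rcpp::export(name = ".lzw_decompress")]]
RawVector lzw_decompress_cpp(RawVector input) {
  const R_xlen_t n = input.size();
  if (n < 3 || input[0] != 0x1F || input[1] != 0x9D)
    stop("not a .Z (compress) stream: bad magic bytes");
  const int maxbits = input[2] & 0x1F;
  const bool block = (input[2] & 0x80) != 0;
  if (maxbits < 9 || maxbits > 16)
    stop("not a .Z (compress) stream: unsupported maxbits %d", maxbits);

  const uint8_t* payload = &input[0] + 3;
  const long nbits_total = 8L * (n - 3);
  int n_bits = 9;
  long maxcode = (1L << n_bits) - 1;
  const long maxmax = 1L << maxbits;
  long free_ent = block ? kFirst : 256;

  std::vector<long> prefix(maxmax, 0);
  std::vector<uint8_t> suffix(maxmax, 0);
  for (int i = 0; i < 256; ++i) suffix[i] = static_cast<uint8_t>(i);

  long posbits = 0;
  long seg_start = 0;   // bit offset where the current width segment began
  long oldcode = -1;
  uint8_t finchar = 0;
  std::vector<uint8_t> out;
  out.reserve(4 * static_cast<size_t>(n));
  std::vector<uint8_t> stack;

  auto get_code = [&](int nb) -> long {
    if (posbits + nb > nbits_total) return -1;
    const long byte_i = posbits >> 3;
    uint32_t chunk = payload[byte_i];
    if (byte_i + 1 < n - 3) chunk |= static_cast<uint32_t>(payload[byte_i + 1]) << 8;
    if (byte_i + 2 < n - 3) chunk |= static_cast<uint32_t>(payload[byte_i + 2]) << 16;
    const long code = (chunk >> (posbits & 7)) & ((1L << nb) - 1);
    posbits += nb;
    return code;
  };
  // round up to an n_bits-byte code-group boundary, relative to the start
  // of the current width segment (matches the reference coder's buffering)
  auto realign = [&]() {
    const long g = static_cast<long>(n_bits) << 3;
    const long rel = posbits - seg_start;
    posbits = seg_start + ((rel + g - 1) / g) * g;
    seg_start = posbits;
  };

  while (true) {
    if (free_ent > maxcode) {
      realign();
      ++n_bits;
      maxcode = (n_bits == maxbits) ? maxmax : (1L << n_bits) - 1;
    }
    long code = get_code(n_bits);
    if (code < 0) break;
    if (oldcode == -1) {
      if (code >= 256) stop("corrupt .Z stream: first code not a literal");
      finchar = static_cast<uint8_t>(code);
      oldcode = code;
      out.push_back(finchar);
      continue;
    }
    if (code == kClear && block) {
      free_ent = kFirst;
      realign();
      n_bits = 9;
      maxcode = (1L << n_bits) - 1;
      code = get_code(n_bits);
      if (code < 0) break;
      if (code >= 256) stop("corrupt .Z stream: post-CLEAR code not a literal");
      finchar = static_cast<uint8_t>(code);
      oldcode = code;
      out.push_back(finchar);
      continue;
    }
    const long incode = code;
    stack.clear();
    if (code >= free_ent) {           // KwKwK case
      if (code > free_ent) stop("corrupt .Z stream: code out of range");
      stack.push_back(finchar);
      code = oldcode;
    }
    while (code >= 256) {
      stack.push_back(suffix[code]);
      code = prefix[code];
    }
    finchar = suffix[code];
    stack.push_back(finchar);
    out.insert(out.end(), stack.rbegin(), stack.rend());
    if (free_ent < maxmax) {
      prefix[free_ent] = oldcode;
      suffix[free_ent] = finchar;
      ++free_ent;
    }
    oldcode = incode;
  }
  return RawVector(out.begin(), out.end());
}
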