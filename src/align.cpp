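#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// k-mer hash index over the forward strand of every chromosome.
// Positions are 0-based; k-mers containing non-ACGT bases are not indexed.
// Reverse-strand queries are handled at query time by aligning the reverse
// complement of the query against forward coordinates.

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

struct FsIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // lexicographic rank of each chromosome name, for deterministic output order
  std::vector<int> name_rank;
  std::unordered_map<uint64_t, std::vector<uint64_t>> kmap; // kmer -> packed hits

  static uint64_t pack(uint32_t chrom, uint64_t pos) {
    return (static_cast<uint64_t>(chrom) << 40) | pos;
  }
  static uint32_t chrom_of(uint64_t h) { return static_cast<uint32_t>(h >> 40); }
  static uint64_t pos_of(uint64_t h)   { return h & ((1ULL << 40) - 1); }
};

struct Hit {
  int chrom;      // 0-based chromosome index
  long start;     // 0-based
  char strand;    // '+' or '-'
  int mism;
};

// mismatches between query (already oriented) and genome at [start, start+L);
// any non-ACGT base on either side counts as a mismatch.
int count_mm(const std::string& g, long start, const std::string& q, int cap) {
  int mm = 0;
  const size_t L = q.size();
  for (size_t i = 0; i < L; ++i) {
    char gc = g[start + i], qc = q[i];
    if (gc != qc || base_code(gc) < 0 || base_code(qc) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

} // namespace

// [[Rcpp::export(name = ".fs_index_build")]]
SEXP fs_index_build(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (names.size() != seqs.size()) stop("names/seqs length mismatch");
  FsIndex* idx = new FsIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < names.size(); ++i) {
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(as<std::string>(seqs[i]));
    if (idx->seqs.back().size() < static_cast<size_t>(k))
      stop("k (%d) exceeds length of chromosome '%s'", k, idx->names.back().c_str());
  }
  // lexicographic ranks of chromosome names
  {
    std::vector<int> ord(idx->names.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return idx->names[a] < idx->names[b];
    });
    idx->name_rank.resize(ord.size());
    for (size_t r = 0; r < ord.size(); ++r) idx->name_rank[ord[r]] = r;
  }
  const uint64_t mask = (k == 31) ? ~0ULL >> 2 : (1ULL << (2 * k)) - 1;
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string& s = idx->seqs[c];
    uint64_t kmer = 0;
    int run = 0; // length of current valid-base run ending here
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | b) & mask;
      if (++run >= k)
        idx->kmap[kmer].push_back(FsIndex::pack(c, i - k + 1));
    }
  }
  XPtr<FsIndex> p(idx, true);
  return p;
}

// [[Rcpp::export(name = ".fs_index_info")]]
List fs_index_info(SEXP xp) {
  XPtr<FsIndex> idx(xp);
  return List::create(_["k"] = idx->k,
                      _["chromosomes"] = wrap(idx->names),
                      _["n_kmers"] = static_cast<double>(idx->kmap.size()));
}

// Align each query against the indexed genome, both strands, gap-free,
// allowing up to max_mm mismatches. Seeds are taken at query offsets
// 0, k, 2k, ... plus the final offset len-k (pigeonhole: complete whenever
// the query holds an error-free k-mer at one of those offsets, guaranteed
// for (max_mm + 1) * k <= len). Results per query are sorted by
// (chromosome name, position, strand; '+' < '-') and truncated to
// max_hits + 1 entries so callers can detect "more than max_hits".
// [[Rcpp::export(name = ".fs_align_batch")]]
DataFrame fs_align_batch(SEXP xp, CharacterVector queries, int max_mm, int max_hits) {
  XPtr<FsIndex> idx(xp);
  const int k = idx->k;
  std::vector<int> out_query, out_chrom, out_mm;
  std::vector<double> out_start;
  std::vector<std::string> out_strand;

  std::vector<Hit> hits;
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    const std::string q = as<std::string>(queries[qi]);
    const long L = static_cast<long>(q.size());
    if (L < k) continue;
    hits.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string s = strand ? revcomp(q) : q;
      seen.clear();
      std::vector<long> offs;
      for (long o = 0; o + k <= L; o += k) offs.push_back(o);
      if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);
      const uint64_t mask = (k == 31) ? ~0ULL >> 2 : (1ULL << (2 * k)) - 1;
      for (long off : offs) {
        uint64_t kmer = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = base_code(s[off + j]);
          if (b < 0) { ok = false; break; }
          kmer = ((kmer << 2) | b) & mask;
        }
        if (!ok) continue;
        auto it = idx->kmap.find(kmer);
        if (it == idx->kmap.end()) continue;
        for (uint64_t h : it->second) {
          const uint32_t c = FsIndex::chrom_of(h);
          const long start = static_cast<long>(FsIndex::pos_of(h)) - off;
          if (start < 0 ||
              start + L > static_cast<long>(idx->seqs[c].size())) continue;
          if (!seen.insert(FsIndex::pack(c, static_cast<uint64_t>(start))).second)
            continue;
          int mm = count_mm(idx->seqs[c], start, s, max_mm);
          if (mm <= max_mm)
            hits.push_back({static_cast<int>(c), start, strand ? '-' : '+', mm});
        }
      }
    }
    std::sort(hits.begin(), hits.end(), [&](const Hit& a, const Hit& b) {
      if (idx->name_rank[a.chrom] != idx->name_rank[b.chrom])
        return idx->name_rank[a.chrom] < idx->name_rank[b.chrom];
      if (a.start != b.start) return a.start < b.start;
      return a.strand < b.strand;
    });
    size_t keep = hits.size();
    if (max_hits >= 0 && keep > static_cast<size_t>(max_hits) + 1)
      keep = static_cast<size_t>(max_hits) + 1;
    for (size_t i = 0; i < keep; ++i) {
      out_query.push_back(qi + 1);
      out_chrom.push_back(hits[i].chrom + 1);
      out_start.push_back(static_cast<double>(hits[i].start));
      out_strand.push_back(std::string(1, hits[i].strand));
      out_mm.push_back(hits[i].mism);
    }
  }
  return DataFrame::create(_["query"] = out_query,
                           _["chrom_idx"] = out_chrom,
                           _["start"] = out_start,
                           _["strand"] = out_strand,
                           _["mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".fs_revcomp")]]
CharacterVector fs_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.attr("names") = x.attr("names");
  return out;
}
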