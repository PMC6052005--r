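#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <queue>
#include <algorithm>
#include <cstdio>
#include "seq_common.h"

using namespace Rcpp;

// Greedy overlap-layout-consensus: repeatedly merge the pair of contigs with
// the longest qualifying overlap (shared-kmer diagonal seeds, ungapped
// mismatch-tolerant verification, both orientations), consensus by per-column
// majority with quality-weighted tie-break. Deterministic: ties broken
// lexicographically by contig id.

namespace {

struct Member { int read; int offset; bool rc; };

struct Ctg {
    std::string id, seq;
    std::vector<Member> members;
    bool active;
};

struct Ovl {
    int len;
    std::string a_id, b_id;   // a_id < b_id lexicographically
    int a, b;                 // contig indices at push time
    bool b_rc;                // B reverse-complemented relative to A
    int pb;                   // position of (oriented) B[0] in A coordinates
};

struct OvlWorse {
    bool operator()(const Ovl &x, const Ovl &y) const {
        if (x.len != y.len) return x.len < y.len;          // longest first
        if (x.a_id != y.a_id) return x.a_id > y.a_id;
        if (x.b_id != y.b_id) return x.b_id > y.b_id;
        if (x.b_rc != y.b_rc) return x.b_rc;               // forward first
        return x.pb > y.pb;
    }
};

struct Assembly {
    int k, stride, min_overlap, max_occ;
    double min_identity;
    std::vector<std::string> rseq, rqual;
    std::vector<Ctg> ctgs;
    std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
    std::priority_queue<Ovl, std::vector<Ovl>, OvlWorse> heap;

    void index_contig(int c) {
        const std::string &s = ctgs[c].seq;
        int L = (int)s.size();
        if (L < k) return;
        uint64_t kmer = 0, mask = (1ULL << (2 * k)) - 1;
        int valid = 0;
        for (int i = 0; i < L; ++i) {
            int b = base2bit(s[i]);
            if (b < 0) { valid = 0; kmer = 0; continue; }
            kmer = ((kmer << 2) | (uint64_t)b) & mask;
            ++valid;
            int p = i - k + 1;
            if (valid >= k && (p % stride) == 0) index[kmer].push_back({c, p});
        }
    }

    // evaluate ungapped overlap of (oriented) B placed at pb in A coords
    bool eval_overlap(int a, int b, bool b_rc, int pb, int &len_out) {
        const std::string &A = ctgs[a].seq;
        std::string B = b_rc ? revcomp(ctgs[b].seq) : ctgs[b].seq;
        int La = (int)A.size(), Lb = (int)B.size();
        int lo = std::max(0, pb), hi = std::min(La, pb + Lb);
        int span = hi - lo;
        if (span < min_overlap) return false;
        int matches = 0;
        for (int p = lo; p < hi; ++p)
            if (bases_match(A[p], B[p - pb])) ++matches;
        if ((double)matches / (double)span < min_identity) return false;
        len_out = span;
        return true;
    }

    // find overlaps of contig x against previously indexed active contigs
    void find_overlaps(int x) {
        const std::string &s = ctgs[x].seq;
        for (int orient = 0; orient < 2; ++orient) {
            std::string q = orient ? revcomp(s) : s;
            int m = (int)q.size();
            if (m < k) continue;
            // votes: (target contig, diag = tpos - qpos)
            std::map<std::pair<int, int>, int> votes;
            uint64_t kmer = 0, mask = (1ULL << (2 * k)) - 1;
            int valid = 0;
            for (int i = 0; i < m; ++i) {
                int b = base2bit(q[i]);
                if (b < 0) { valid = 0; kmer = 0; continue; }
                kmer = ((kmer << 2) | (uint64_t)b) & mask;
                ++valid;
                if (valid < k) continue;
                int qpos = i - k + 1;
                auto it = index.find(kmer);
                if (it == index.end()) continue;
                if ((int)it->second.size() > max_occ) continue;
                for (auto &pr : it->second) {
                    if (pr.first == x || !ctgs[pr.first].active) continue;
                    votes[{pr.first, pr.second - qpos}]++;
                }
            }
            for (auto &kv : votes) {
                int y = kv.first.first, d = kv.first.second;
                // oriented-x aligned into y at offset d; normalize so A has the
                // lexicographically smaller id and only B may be flipped
                int a, b; bool b_rc; int pb;
                int Lx = (int)ctgs[x].seq.size(), Ly = (int)ctgs[y].seq.size();
                bool x_is_a = ctgs[x].id < ctgs[y].id;
                if (x_is_a) {
                    a = x; b = y;
                    if (orient == 0) { b_rc = false; pb = -d; }
                    else             { b_rc = true;  pb = d + Lx - Ly; }
                } else {
                    a = y; b = x;
                    b_rc = (orient == 1); pb = d;
                }
                int len;
                if (eval_overlap(a, b, b_rc, pb, len))
                    heap.push({len, ctgs[a].id, ctgs[b].id, a, b, b_rc, pb});
            }
        }
    }

    std::string consensus(const std::vector<Member> &members, int len) {
        std::string out(len, 'N');
        std::vector<int> cnt(4), qw(4);
        // column-major would rescan; do per-column via precomputed oriented reads
        std::vector<std::string> oseq(members.size()), oqual(members.size());
        for (size_t i = 0; i < members.size(); ++i) {
            const Member &mb = members[i];
            oseq[i] = mb.rc ? revcomp(rseq[mb.read]) : rseq[mb.read];
            std::string q = rqual[mb.read];
            if (q.empty()) q = std::string(oseq[i].size(), '?');   // phred 30
            else if (mb.rc) std::reverse(q.begin(), q.end());
            oqual[i] = q;
        }
        std::vector<std::vector<std::pair<int, int>>> cov(len);
        for (size_t i = 0; i < members.size(); ++i)
            for (int p = 0; p < (int)oseq[i].size(); ++p) {
                int col = members[i].offset + p;
                if (col >= 0 && col < len) cov[col].push_back({(int)i, p});
            }
        for (int col = 0; col < len; ++col) {
            std::fill(cnt.begin(), cnt.end(), 0);
            std::fill(qw.begin(), qw.end(), 0);
            for (auto &pr : cov[col]) {
                int i = pr.first, p = pr.second;
                int b = base2bit(oseq[i][p]);
                if (b < 0) continue;
                cnt[b]++; qw[b] += (int)oqual[i][p] - 33;
            }
            int best = -1;
            for (int b = 0; b < 4; ++b) {
                if (cnt[b] == 0) continue;
                if (best < 0 || cnt[b] > cnt[best] ||
                    (cnt[b] == cnt[best] && qw[b] > qw[best]))
                    best = b;  // equal count and weight: lower b (lexicographic) kept
            }
            if (best >= 0) out[col] = "ACGT"[best];
        }
        return out;
    }

    void merge(const Ovl &o, int &counter) {
        Ctg &A = ctgs[o.a], &B = ctgs[o.b];
        int La = (int)A.seq.size(), Lb = (int)B.seq.size();
        std::vector<Member> mem = A.members;
        for (Member mb : B.members) {
            if (o.b_rc) {
                int rl = (int)rseq[mb.read].size();
                mb.offset = Lb - mb.offset - rl;
                mb.rc = !mb.rc;
            }
            mb.offset += o.pb;
            mem.push_back(mb);
        }
        int shift = std::min(0, o.pb);
        for (Member &mb : mem) mb.offset -= shift;
        int len = std::max(La, o.pb + Lb) - shift;
        Ctg nc;
        char buf[16];
        snprintf(buf, sizeof(buf), "m%07d", counter++);
        nc.id = buf;
        nc.members = mem;
        nc.seq = consensus(mem, len);
        nc.active = true;
        A.active = false; B.active = false;
        ctgs.push_back(nc);
        int ni = (int)ctgs.size() - 1;
        find_overlaps(ni);
        index_contig(ni);
    }
};

} // namespace

// [[Rcpp::export]]
List cpp_assemble_greedy(CharacterVector ids, CharacterVector seqs,
                         CharacterVector quals, int min_overlap,
                         double min_identity, int k, int stride, int max_occ) {
    int n = seqs.size();
    Assembly eng;
    eng.k = k; eng.stride = stride; eng.min_overlap = min_overlap;
    eng.min_identity = min_identity; eng.max_occ = max_occ;
    for (int i = 0; i < n; ++i) {
        eng.rseq.push_back(as<std::string>(seqs[i]));
        eng.rqual.push_back(STRING_ELT(quals, i) == NA_STRING
                               ? std::string()
                               : as<std::string>(quals[i]));
        Ctg c;
        c.id = as<std::string>(ids[i]);
        c.seq = eng.rseq.back();
        c.members = {{i, 0, false}};
        c.active = true;
        eng.ctgs.push_back(c);
    }
    // initial all-pairs candidates: query each contig against those already
    // indexed, so every unordered pair is considered exactly once
    for (int i = 0; i < n; ++i) {
        eng.find_overlaps(i);
        eng.index_contig(i);
    }
    int counter = 0, ops = 0;
    while (!eng.heap.empty()) {
        Ovl o = eng.heap.top(); eng.heap.pop();
        if (!eng.ctgs[o.a].active || !eng.ctgs[o.b].active) continue;
        eng.merge(o, counter);
        if (++ops % 64 == 0) Rcpp::checkUserInterrupt();
    }
    std::vector<std::string> out_seq;
    std::vector<int> out_nreads;
    std::vector<int> mem_ctg, mem_read, mem_off;
    std::vector<bool> mem_rc;
    int oc = 0;
    for (auto &c : eng.ctgs) {
        if (!c.active) continue;
        ++oc;
        out_seq.push_back(c.seq);
        out_nreads.push_back((int)c.members.size());
        for (auto &mb : c.members) {
            mem_ctg.push_back(oc);            // 1-based output contig index
            mem_read.push_back(mb.read + 1);  // 1-based input index
            mem_off.push_back(mb.offset);
            mem_rc.push_back(mb.rc);
        }
    }
    return List::create(
        _["sequence"] = wrap(out_seq),
        _["n_reads"] = wrap(out_nreads),
        _["members"] = DataFrame::create(_["contig"] = wrap(mem_ctg),
                                         _["read"] = wrap(mem_read),
                                         _["offset"] = wrap(mem_off),
                                         _["rc"] = wrap(mem_rc),
                                         _["stringsAsFactors"] = false));
}
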