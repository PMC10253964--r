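// Incremental isotropic remeshing: iterated edge split / collapse / flip with
// tangential Laplacian relaxation and projection back onto the input surface
// (Botsch & Kobbelt style). Closed manifold triangle meshes.
#include "trigrid.h"
#include <unordered_map>
#include <unordered_set>
#include <array>
using namespace Rcpp;
using namespace ssmesh;

namespace {

struct EdgeRec {
  int a, b;          // a < b
  int nf = 0;        // number of adjacent faces seen
  int face[2] = {-1, -1};
  int opp[2] = {-1, -1};
};

typedef long long EKey;
inline EKey ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return ((EKey)a << 32) | (EKey)(unsigned)b;
}

// small deterministic PRNG for triangulation jitter
struct XorShift {
  unsigned long long s;
  explicit XorShift(unsigned long long seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  double unif() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return (double)(s >> 11) / 9007199254740992.0;
  }
};

struct WorkMesh {
  std::vector<Vec3> V;
  std::vector<bool> vAlive;
  std::vector<std::array<int, 3>> F;

  std::unordered_map<EKey, EdgeRec> edges;
  std::vector<std::vector<int>> vnbr;  // vertex -> neighbor vertices

  void buildEdges() {
    edges.clear();
    edges.reserve(F.size() * 2);
    for (int f = 0; f < (int)F.size(); ++f) {
      for (int k = 0; k < 3; ++k) {
        int a = F[f][k], b = F[f][(k + 1) % 3], c = F[f][(k + 2) % 3];
        EdgeRec& e = edges[ekey(a, b)];
        if (e.nf == 0) { e.a = std::min(a, b); e.b = std::max(a, b); }
        if (e.nf < 2) { e.face[e.nf] = f; e.opp[e.nf] = c; }
        e.nf++;
      }
    }
  }

  void buildNeighbors() {
    vnbr.assign(V.size(), {});
    for (const auto& kv : edges) {
      vnbr[kv.second.a].push_back(kv.second.b);
      vnbr[kv.second.b].push_back(kv.second.a);
    }
  }

  double elen(int a, int b) const { return std::sqrt(norm2(V[a] - V[b])); }

  int nAliveVerts() const {
    int n = 0;
    for (bool a : vAlive) n += a;
    return n;
  }

  // --- split all edges longer than high, repeated sweeps ---
  void splitLong(double high) {
    for (int sweep = 0; sweep < 12; ++sweep) {
      buildEdges();
      std::vector<const EdgeRec*> longEdges;
      for (const auto& kv : edges)
        if (kv.second.nf == 2 && elen(kv.second.a, kv.second.b) > high)
          longEdges.push_back(&kv.second);
      if (longEdges.empty()) break;
      std::vector<bool> faceTouched(F.size(), false);
      bool any = false;
      for (const EdgeRec* e : longEdges) {
        int f0 = e->face[0], f1 = e->face[1];
        if (faceTouched[f0] || faceTouched[f1]) continue;
        int a = e->a, b = e->b;
        int m = (int)V.size();
        V.push_back((V[a] + V[b]) * 0.5);
        vAlive.push_back(true);
        for (int fi : {f0, f1}) {
          std::array<int, 3> tri = F[fi];
          // find edge (a,b) in tri, split into two faces preserving orientation
          for (int k = 0; k < 3; ++k) {
            int u = tri[k], v = tri[(k + 1) % 3], w = tri[(k + 2) % 3];
            if ((u == a && v == b) || (u == b && v == a)) {
              F[fi] = {u, m, w};
              F.push_back({m, v, w});
              faceTouched.push_back(true);
              break;
            }
          }
          faceTouched[fi] = true;
        }
        any = true;
      }
      if (!any) break;
    }
  }

  // --- collapse edges shorter than low (midpoint), manifold-safe ---
  void collapseShort(double low, double high, int minVerts) {
    for (int sweep = 0; sweep < 4; ++sweep) {
      buildEdges();
      buildNeighbors();
      std::vector<bool> vTouched(V.size(), false);
      bool any = false;
      int alive = nAliveVerts();
      for (auto& kv : edges) {
        const EdgeRec& e = kv.second;
        if (e.nf != 2) continue;
        int a = e.a, b = e.b;
        if (vTouched[a] || vTouched[b]) continue;
        if (alive <= minVerts) break;
        if (elen(a, b) >= low) continue;
        // link condition: common neighbors of a and b must be exactly the
        // two opposite vertices
        std::unordered_set<int> na(vnbr[a].begin(), vnbr[a].end());
        int nCommon = 0;
        bool ok = true;
        for (int x : vnbr[b]) {
          if (na.count(x)) {
            ++nCommon;
            if (x != e.opp[0] && x != e.opp[1]) { ok = false; break; }
          }
        }
        if (!ok || nCommon != 2) continue;
        // don't create overlong edges
        Vec3 mid = (V[a] + V[b]) * 0.5;
        for (int x : vnbr[a]) if (x != b && std::sqrt(norm2(V[x] - mid)) > high) { ok = false; break; }
        if (ok) for (int x : vnbr[b]) if (x != a && std::sqrt(norm2(V[x] - mid)) > high) { ok = false; break; }
        if (!ok) continue;
        // collapse b into a at midpoint
        V[a] = mid;
        vAlive[b] = false;
        --alive;
        for (int f = 0; f < (int)F.size(); ++f) {
          bool hasA = false, hasB = false;
          for (int k = 0; k < 3; ++k) { hasA |= F[f][k] == a; hasB |= F[f][k] == b; }
          if (hasA && hasB) F[f] = {-1, -1, -1};  // degenerate, drop
          else if (hasB) for (int k = 0; k < 3; ++k) if (F[f][k] == b) F[f][k] = a;
        }
        dropDeadFaces();
        vTouched[a] = true; vTouched[b] = true;
        for (int x : vnbr[a]) vTouched[x] = true;
        for (int x : vnbr[b]) vTouched[x] = true;
        any = true;
      }
      if (!any) break;
    }
  }

  void dropDeadFaces() {
    size_t w = 0;
    for (size_t f = 0; f < F.size(); ++f)
      if (F[f][0] >= 0) F[w++] = F[f];
    F.resize(w);
  }

  // --- valence-equalizing edge flips ---
  void flipForValence() {
    for (int sweep = 0; sweep < 3; ++sweep) {
      buildEdges();
      std::vector<int> val(V.size(), 0);
      for (const auto& kv : edges) { val[kv.second.a]++; val[kv.second.b]++; }
      std::vector<bool> vTouched(V.size(), false);
      bool any = false;
      for (const auto& kv : edges) {
        const EdgeRec& e = kv.second;
        if (e.nf != 2) continue;
        int a = e.a, b = e.b, c = e.opp[0], d = e.opp[1];
        if (c == d || c < 0 || d < 0) continue;
        if (vTouched[a] || vTouched[b] || vTouched[c] || vTouched[d]) continue;
        if (edges.count(ekey(c, d))) continue;  // flip would duplicate an edge
        auto dev = [&](int va, int vb, int vc, int vd) {
          auto sq = [](int x) { return x * x; };
          return sq(va - 6) + sq(vb - 6) + sq(vc - 6) + sq(vd - 6);
        };
        int before = dev(val[a], val[b], val[c], val[d]);
        int after = dev(val[a] - 1, val[b] - 1, val[c] + 1, val[d] + 1);
        if (after >= before) continue;
        // geometric guard: new triangles must not be degenerate or folded
        Vec3 n1 = cross(V[b] - V[a], V[c] - V[a]);
        Vec3 n2 = cross(V[a] - V[b], V[d] - V[b]);
        Vec3 m1 = cross(V[d] - V[a], V[c] - V[d]);
        Vec3 m2 = cross(V[b] - V[d], V[c] - V[b]);
        double ref = std::sqrt(norm2(n1)) + std::sqrt(norm2(n2));
        if (std::sqrt(norm2(m1)) < 1e-4 * ref || std::sqrt(norm2(m2)) < 1e-4 * ref) continue;
        Vec3 nsum = n1 + n2;
        if (dot(m1, nsum) <= 0 || dot(m2, nsum) <= 0) continue;
        // locate faces and rewrite: (a,b,c),(b,a,d) -> (a,d,c),(d,b,c)
        int f0 = e.face[0], f1 = e.face[1];
        // determine which face has orientation a->b
        auto hasDirected = [&](int f, int u, int v) {
          for (int k = 0; k < 3; ++k)
            if (F[f][k] == u && F[f][(k + 1) % 3] == v) return true;
          return false;
        };
        int fab = hasDirected(f0, a, b) ? f0 : f1;
        int fba = fab == f0 ? f1 : f0;
        if (!hasDirected(fab, a, b) || !hasDirected(fba, b, a)) continue;
        int cc = e.opp[fab == e.face[0] ? 0 : 1];
        int dd = e.opp[fab == e.face[0] ? 1 : 0];
        F[fab] = {a, dd, cc};
        F[fba] = {dd, b, cc};
        val[a]--; val[b]--; val[cc]++; val[dd]++;
        vTouched[a] = vTouched[b] = vTouched[cc] = vTouched[dd] = true;
        any = true;
      }
      if (!any) break;
    }
  }

  // --- tangential relaxation + projection onto reference surface ---
  void relax(const TriGrid& ref, double jitter, XorShift& rng) {
    buildEdges();
    buildNeighbors();
    // area-weighted vertex normals
    std::vector<Vec3> vn(V.size());
    for (const auto& tri : F) {
      Vec3 n = cross(V[tri[1]] - V[tri[0]], V[tri[2]] - V[tri[0]]);
      for (int k = 0; k < 3; ++k) vn[tri[k]] = vn[tri[k]] + n;
    }
    std::vector<Vec3> newV = V;
    for (int i = 0; i < (int)V.size(); ++i) {
      if (!vAlive[i] || vnbr[i].empty()) continue;
      Vec3 g(0, 0, 0);
      for (int x : vnbr[i]) g = g + V[x];
      g = g * (1.0 / vnbr[i].size());
      Vec3 n = vn[i];
      double nn = std::sqrt(norm2(n));
      if (nn > 0) n = n * (1.0 / nn);
      Vec3 dpl = g - V[i];
      dpl = dpl - n * dot(n, dpl);  // tangential component only
      Vec3 p = V[i] + dpl;
      if (jitter > 0) {
        Vec3 r(rng.unif() - 0.5, rng.unif() - 0.5, rng.unif() - 0.5);
        r = r - n * dot(n, r);
        p = p + r * jitter;
      }
      Vec3 cp;
      ref.query(p, cp);
      newV[i] = cp;
    }
    V = newV;
  }

  void compact(std::vector<Vec3>& Vout, std::vector<std::array<int, 3>>& Fout) {
    std::vector<int> remap(V.size(), -1);
    Vout.clear();
    for (int i = 0; i < (int)V.size(); ++i)
      if (vAlive[i]) { remap[i] = (int)Vout.size(); Vout.push_back(V[i]); }
    Fout.clear();
    for (const auto& tri : F) {
      std::array<int, 3> t = {remap[tri[0]], remap[tri[1]], remap[tri[2]]};
      if (t[0] >= 0 && t[1] >= 0 && t[2] >= 0) Fout.push_back(t);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_remesh")]]
List cpp_remesh(NumericMatrix Vm, IntegerMatrix Fm, double target_len,
                int n_iterations, double jitter, int seed,
                NumericMatrix features) {
  WorkMesh m;
  int nV = Vm.nrow(), nF = Fm.nrow();
  m.V.resize(nV);
  for (int i = 0; i < nV; ++i) m.V[i] = Vec3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
  m.vAlive.assign(nV, true);
  m.F.resize(nF);
  for (int f = 0; f < nF; ++f) m.F[f] = {Fm(f, 0), Fm(f, 1), Fm(f, 2)};

  // reference surface for projection
  std::vector<int> Fflat(3 * nF);
  for (int f = 0; f < nF; ++f) {
    Fflat[3 * f] = Fm(f, 0); Fflat[3 * f + 1] = Fm(f, 1); Fflat[3 * f + 2] = Fm(f, 2);
  }
  TriGrid ref;
  ref.build(m.V, Fflat);

  XorShift rng((unsigned long long)seed * 2654435761ULL + 1ULL);
  double high = 4.0 / 3.0 * target_len, low = 4.0 / 5.0 * target_len;
  int nFeat = features.nrow();
  for (int it = 0; it < n_iterations; ++it) {
    m.splitLong(high);
    m.collapseShort(low, high, 4);
    m.flipForValence();
    m.relax(ref, it == 0 ? jitter * target_len : 0.0, rng);
    // snap the nearest vertex onto each sharp feature point so apexes
    // of the input surface are preserved exactly
    for (int k = 0; k < nFeat; ++k) {
      Vec3 p(features(k, 0), features(k, 1), features(k, 2));
      double best = std::numeric_limits<double>::infinity();
      int bi = -1;
      for (int i = 0; i < (int)m.V.size(); ++i) {
        if (!m.vAlive[i]) continue;
        double d2 = norm2(m.V[i] - p);
        if (d2 < best) { best = d2; bi = i; }
      }
      if (bi >= 0 && best < target_len * target_len) m.V[bi] = p;
    }
    Rcpp::checkUserInterrupt();
  }

  std::vector<Vec3> Vout;
  std::vector<std::array<int, 3>> Fout;
  m.compact(Vout, Fout);
  NumericMatrix Vr((int)Vout.size(), 3);
  for (int i = 0; i < (int)Vout.size(); ++i) {
    Vr(i, 0) = Vout[i].x; Vr(i, 1) = Vout[i].y; Vr(i, 2) = Vout[i].z;
  }
  IntegerMatrix Fr((int)Fout.size(), 3);
  for (int f = 0; f < (int)Fout.size(); ++f) {
    Fr(f, 0) = Fout[f][0]; Fr(f, 1) = Fout[f][1]; Fr(f, 2) = Fout[f][2];
  }
  return List::create(_["vertices"] = Vr, _["faces"] = Fr);
}
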