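// Shared triangle-mesh spatial-grid utilities (closest point on surface).
#ifndef SSMESH_TRIGRID_H
#define SSMESH_TRIGRID_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

namespace ssmesh {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm2(const Vec3& a) { return dot(a, a); }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
inline Vec3 closestOnTri(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) return a + ab * (d1 / (d1 - d3));
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) return a + ac * (d2 / (d2 - d6));
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  return a + ab * (vb * denom) + ac * (vc * denom);
}

struct TriGrid {
  std::vector<Vec3> V;
  std::vector<int> F;  // 3 * nF
  int nF = 0;
  double h = 1.0, ox = 0, oy = 0, oz = 0;
  int nx = 1, ny = 1, nz = 1;
  std::vector<std::vector<int>> cells;

  int cellIndex(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }
  static int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

  void build(const std::vector<Vec3>& Vin, const std::vector<int>& Fin) {
    V = Vin;
    F = Fin;
    nF = (int)F.size() / 3;
    double minx = std::numeric_limits<double>::infinity(), miny = minx, minz = minx;
    double maxx = -minx, maxy = -minx, maxz = -minx;
    for (const Vec3& v : V) {
      minx = std::min(minx, v.x); maxx = std::max(maxx, v.x);
      miny = std::min(miny, v.y); maxy = std::max(maxy, v.y);
      minz = std::min(minz, v.z); maxz = std::max(maxz, v.z);
    }
    double meanEdge = 0.0;
    for (int f = 0; f < nF; ++f)
      meanEdge += std::sqrt(norm2(V[F[3 * f]] - V[F[3 * f + 1]]));
    meanEdge = nF > 0 ? meanEdge / nF : 1.0;
    double dx = maxx - minx, dy = maxy - miny, dz = maxz - minz;
    double diag = std::sqrt(dx * dx + dy * dy + dz * dz);
    h = std::max(meanEdge, diag / 128.0);
    if (!(h > 0)) h = 1.0;
    ox = minx - 0.5 * h; oy = miny - 0.5 * h; oz = minz - 0.5 * h;
    nx = std::max(1, (int)std::floor((maxx - ox) / h) + 1);
    ny = std::max(1, (int)std::floor((maxy - oy) / h) + 1);
    nz = std::max(1, (int)std::floor((maxz - oz) / h) + 1);
    cells.assign((size_t)nx * ny * nz, {});
    for (int f = 0; f < nF; ++f) {
      const Vec3& a = V[F[3 * f]]; const Vec3& b = V[F[3 * f + 1]]; const Vec3& c = V[F[3 * f + 2]];
      int ix0 = clampi((int)((std::min({a.x, b.x, c.x}) - ox) / h), 0, nx - 1);
      int ix1 = clampi((int)((std::max({a.x, b.x, c.x}) - ox) / h), 0, nx - 1);
      int iy0 = clampi((int)((std::min({a.y, b.y, c.y}) - oy) / h), 0, ny - 1);
      int iy1 = clampi((int)((std::max({a.y, b.y, c.y}) - oy) / h), 0, ny - 1);
      int iz0 = clampi((int)((std::min({a.z, b.z, c.z}) - oz) / h), 0, nz - 1);
      int iz1 = clampi((int)((std::max({a.z, b.z, c.z}) - oz) / h), 0, nz - 1);
      for (int iz = iz0; iz <= iz1; ++iz)
        for (int iy = iy0; iy <= iy1; ++iy)
          for (int ix = ix0; ix <= ix1; ++ix)
            cells[cellIndex(ix, iy, iz)].push_back(f);
    }
  }

  int query(const Vec3& q, Vec3& cp) const {
    int qx = clampi((int)((q.x - ox) / h), 0, nx - 1);
    int qy = clampi((int)((q.y - oy) / h), 0, ny - 1);
    int qz = clampi((int)((q.z - oz) / h), 0, nz - 1);
    double best = std::numeric_limits<double>::infinity();
    int bestF = -1;
    Vec3 bestP;
    int maxRing = std::max({nx, ny, nz});
    for (int ring = 0; ring <= maxRing; ++ring) {
      if (bestF >= 0) {
        double ringDist = (ring - 1) * h;
        if (ringDist > 0 && ringDist * ringDist > best) break;
      }
      int ix0 = clampi(qx - ring, 0, nx - 1), ix1 = clampi(qx + ring, 0, nx - 1);
      int iy0 = clampi(qy - ring, 0, ny - 1), iy1 = clampi(qy + ring, 0, ny - 1);
      int iz0 = clampi(qz - ring, 0, nz - 1), iz1 = clampi(qz + ring, 0, nz - 1);
      for (int iz = iz0; iz <= iz1; ++iz)
        for (int iy = iy0; iy <= iy1; ++iy)
          for (int ix = ix0; ix <= ix1; ++ix) {
            if (ring > 0 &&
                std::abs(ix - qx) != ring && std::abs(iy - qy) != ring &&
                std::abs(iz - qz) != ring) continue;
            const std::vector<int>& cell = cells[cellIndex(ix, iy, iz)];
            if (cell.empty()) continue;
            // prune: squared distance from q to the cell's AABB
            double bx0 = ox + ix * h, by0 = oy + iy * h, bz0 = oz + iz * h;
            double ddx = q.x < bx0 ? bx0 - q.x : (q.x > bx0 + h ? q.x - bx0 - h : 0.0);
            double ddy = q.y < by0 ? by0 - q.y : (q.y > by0 + h ? q.y - by0 - h : 0.0);
            double ddz = q.z < bz0 ? bz0 - q.z : (q.z > bz0 + h ? q.z - bz0 - h : 0.0);
            if (ddx * ddx + ddy * ddy + ddz * ddz > best) continue;
            for (int f : cell) {
              Vec3 p = closestOnTri(q, V[F[3 * f]], V[F[3 * f + 1]], V[F[3 * f + 2]]);
              double d2 = norm2(p - q);
              if (d2 < best) { best = d2; bestF = f; bestP = p; }
            }
          }
    }
    cp = bestP;
    return bestF;
  }
};

}  // namespace ssmesh

#endif
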