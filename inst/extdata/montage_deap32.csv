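# Idealized 10-10 spherical electrode coordinates, 32-channel montage.
# Construction: unit sphere; outer ring at 72 deg inclination with 18 deg
# azimuthal spacing; midline at 18/36/54/72 deg inclination; intermediate
# sites by spherical interpolation along coronal arcs (C3 = midpoint of
# Cz-T7, FC1/FC5 at 1/4 and 3/4 of FCz-FT7, etc.). Frame: azimuth from
# nasion axis, positive toward the left ear; elevation from the horizontal
# plane, vertex (Cz) at 90. Right-hemisphere sites are exact mirrors.
label,azimuth_deg,elevation_deg
Fp1,18,18
AF3,19.502,28.1718
F3,33.8587,38.993
F7,54,18
FC5,65.6221,33.8483
FC1,38.9953,63.177
C3,90,54
T7,90,18
CP5,114.3779,33.8483
CP1,141.0047,63.177
P3,146.1413,38.993
P7,126,18
PO3,160.498,28.1718
O1,162,18
Oz,180,18
Pz,180,54
Fp2,-18,18
AF4,-19.502,28.1718
Fz,0,54
F4,-33.8587,38.993
F8,-54,18
FC6,-65.6221,33.8483
FC2,-38.9953,63.177
Cz,0,90
C4,-90,54
T8,-90,18
CP6,-114.3779,33.8483
CP2,-141.0047,63.177
P4,-146.1413,38.993
P8,-126,18
PO4,-160.498,28.1718
O2,-162,18
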