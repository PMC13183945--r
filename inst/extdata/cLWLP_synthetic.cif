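# Synthetic idealized model of the c-LWLP crystal form (hexagonal P6_3,
# one surrogate molecule per asymmetric unit). Generated by
# cyclohelix::synthetic_cwp_crystal("cLWLP", expand = FALSE). Not an
# experimental structure.
data_cyclohelix
_cell_length_a    14.947400
_cell_length_b    14.947400
_cell_length_c    10.821300
_cell_angle_alpha 90.000000
_cell_angle_beta  90.000000
_cell_angle_gamma 120.000000
loop_
_space_group_symop_operation_xyz
  'x,y,z'
  '-y,x-y,z'
  '-x+y,-x,z'
  '-x,-y,z+1/2'
  'y,-x+y,z+1/2'
  'x-y,x,z+1/2'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_residue
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
N N TRP 0.468309 -0.000000 0.381410
H H TRP 0.415377 -0.052932 0.437924
C C TRP 0.377983 0.285686 0.076390
O O TRP 0.468309 0.313958 0.046205
CA C TRP 0.525108 -0.000000 0.270513
C1 C TRP 0.495683 0.057137 0.231689
C2 C TRP 0.466258 0.114275 0.192864
C3 C TRP 0.436833 0.171412 0.154040
C4 C TRP 0.407408 0.228549 0.115215
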