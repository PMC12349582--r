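code,igbp_class,group
1,Evergreen Needleleaf Forests,non_study
2,Evergreen Broadleaf Forests,non_study
3,Deciduous Needleleaf Forests,non_study
4,Deciduous Broadleaf Forests,forest
5,Mixed Forests,forest
6,Closed Shrublands,non_study
7,Open Shrublands,non_study
8,Woody Savannas,grassland
9,Savannas,grassland
10,Grasslands,grassland
11,Permanent Wetlands,non_study
12,Croplands,farmland
13,Urban and Built-up Lands,non_study
14,Cropland/Natural Vegetation Mosaics,farmland
15,Permanent Snow and Ice,non_study
16,Barren,non_study
17,Water Bodies,non_study
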