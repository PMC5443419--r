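# cytochrome-c-oxidase oxidised-minus-reduced difference spectrum
# synthetic: smooth parametric stand-in anchored to published literature values, not a digitized copy
# units: mM^-1 cm^-1 (base-10 specific absorption, oxidised-minus-reduced difference)
wavelength_nm,value
700,0.663862
702,0.684369
704,0.705643
706,0.727673
708,0.750446
710,0.773947
712,0.798159
714,0.823063
716,0.848641
718,0.874872
720,0.901733
722,0.929204
724,0.95726
726,0.985879
728,1.01504
730,1.04471
732,1.07488
734,1.10552
736,1.13661
738,1.16812
740,1.20003
742,1.23232
744,1.26497
746,1.29795
748,1.33125
750,1.36483
752,1.39867
754,1.43274
756,1.46702
758,1.50148
760,1.53608
762,1.5708
764,1.60558
766,1.6404
768,1.67521
770,1.70996
772,1.7446
774,1.77908
776,1.81333
778,1.8473
780,1.88092
782,1.91412
784,1.94682
786,1.97895
788,2.01042
790,2.04116
792,2.07108
794,2.10008
796,2.12809
798,2.15501
800,2.18075
802,2.20521
804,2.22832
806,2.24999
808,2.27011
810,2.28863
812,2.30544
814,2.32049
816,2.3337
818,2.34499
820,2.35433
822,2.36164
824,2.36689
826,2.37003
828,2.37104
830,2.36989
832,2.36656
834,2.36105
836,2.35336
838,2.3435
840,2.33148
842,2.31733
844,2.30109
846,2.28279
848,2.2625
850,2.24026
852,2.21614
854,2.19021
856,2.16254
858,2.13323
860,2.10236
862,2.07002
864,2.03631
866,2.00133
868,1.96518
870,1.92797
872,1.88981
874,1.85081
876,1.81107
878,1.77071
880,1.72983
882,1.68855
884,1.64697
886,1.60519
888,1.56333
890,1.52147
892,1.47972
894,1.43816
896,1.39689
898,1.35599
900,1.31554
902,1.27562
904,1.2363
906,1.19764
908,1.1597
910,1.12255
912,1.08622
914,1.05077
916,1.01623
918,0.982646
920,0.950039
922,0.918437
924,0.887859
926,0.858322
928,0.829836
930,0.802408
932,0.776041
934,0.750734
936,0.726482
938,0.703278
940,0.68111
942,0.659964
944,0.639824
946,0.620671
948,0.602483
950,0.585237
952,0.568909
954,0.553472
956,0.538899
958,0.525161
960,0.51223
962,0.500074
964,0.488664
966,0.47797
968,0.46796
970,0.458604
972,0.449871
974,0.441731
976,0.434154
978,0.427112
980,0.420575
982,0.414515
984,0.408905
986,0.40372
988,0.398932
990,0.394519
992,0.390455
994,0.386718
996,0.383288
998,0.380141
1000,0.37726
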