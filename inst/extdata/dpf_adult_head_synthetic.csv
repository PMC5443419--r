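# adult-head differential pathlength factor vs wavelength
# synthetic: smooth parametric stand-in anchored to published literature values, not a digitized copy
# units: dimensionless (differential pathlength factor)
wavelength_nm,value
700,6.55
702,6.53756
704,6.52522
706,6.51298
708,6.5008
710,6.48867
712,6.47658
714,6.46449
716,6.4524
718,6.44028
720,6.42812
722,6.4159
724,6.4036
726,6.3912
728,6.37868
730,6.36602
732,6.3532
734,6.34021
736,6.32702
738,6.31363
740,6.3
742,6.28609
744,6.27188
746,6.25739
748,6.24267
750,6.22773
752,6.21263
754,6.19737
756,6.182
758,6.16655
760,6.15104
762,6.13552
764,6.12
766,6.10453
768,6.08912
770,6.07383
772,6.05867
774,6.04367
776,6.02888
778,6.01431
780,6
782,5.98584
784,5.9717
786,5.9576
788,5.94357
790,5.92963
792,5.9158
794,5.9021
796,5.88856
798,5.8752
800,5.86204
802,5.8491
804,5.8364
806,5.82397
808,5.81183
810,5.8
812,5.78859
814,5.77766
816,5.76715
818,5.75701
820,5.74719
822,5.73762
824,5.72826
826,5.71904
828,5.70992
830,5.70083
832,5.69173
834,5.68256
836,5.67326
838,5.66378
840,5.65406
842,5.64405
844,5.6337
846,5.62294
848,5.61173
850,5.6
852,5.58777
854,5.57509
856,5.56201
858,5.54857
860,5.5348
862,5.52074
864,5.50644
866,5.49192
868,5.47723
870,5.4624
872,5.44748
874,5.4325
876,5.4175
878,5.40252
880,5.3876
882,5.37277
884,5.35808
886,5.34356
888,5.32926
890,5.3152
892,5.30143
894,5.28799
896,5.27491
898,5.26223
900,5.25
902,5.23812
904,5.22647
906,5.21504
908,5.20382
910,5.1928
912,5.18197
914,5.17133
916,5.16086
918,5.15055
920,5.1404
922,5.13039
924,5.12052
926,5.11076
928,5.10113
930,5.0916
932,5.08217
934,5.07282
936,5.06355
938,5.05435
940,5.0452
942,5.0361
944,5.02704
946,5.01801
948,5.009
950,5
952,4.99108
954,4.98231
956,4.97368
958,4.96518
960,4.9568
962,4.94853
964,4.94037
966,4.9323
968,4.92431
970,4.9164
972,4.90855
974,4.90076
976,4.893
978,4.88529
980,4.8776
982,4.86993
984,4.86226
986,4.85459
988,4.84691
990,4.8392
992,4.83146
994,4.82368
996,4.81585
998,4.80796
1000,4.8
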