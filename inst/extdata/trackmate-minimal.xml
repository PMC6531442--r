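<?xml version="1.0" encoding="UTF-8"?>
<TrackMate version="7.11.1">
  <Model spatialunits="micron" timeunits="sec">
    <AllSpots nspots="6">
      <SpotsInFrame frame="0">
        <Spot ID="1001" name="ID1001" FRAME="0" POSITION_X="1.00" POSITION_Y="2.00" POSITION_T="0.0" QUALITY="150.0" TOTAL_INTENSITY="900.0" />
        <Spot ID="1004" name="ID1004" FRAME="0" POSITION_X="6.00" POSITION_Y="2.50" POSITION_T="0.0" QUALITY="140.0" TOTAL_INTENSITY="800.0" />
      </SpotsInFrame>
      <SpotsInFrame frame="1">
        <Spot ID="1002" name="ID1002" FRAME="1" POSITION_X="1.20" POSITION_Y="2.10" POSITION_T="10.0" QUALITY="151.0" TOTAL_INTENSITY="910.0" />
        <Spot ID="1005" name="ID1005" FRAME="1" POSITION_X="6.10" POSITION_Y="2.60" POSITION_T="10.0" QUALITY="141.0" TOTAL_INTENSITY="810.0" />
      </SpotsInFrame>
      <SpotsInFrame frame="2">
        <Spot ID="1003" name="ID1003" FRAME="2" POSITION_X="1.40" POSITION_Y="2.20" POSITION_T="20.0" QUALITY="152.0" TOTAL_INTENSITY="920.0" />
        <Spot ID="1006" name="ID1006" FRAME="2" POSITION_X="6.20" POSITION_Y="2.70" POSITION_T="20.0" QUALITY="142.0" TOTAL_INTENSITY="820.0" />
      </SpotsInFrame>
    </AllSpots>
    <AllTracks>
      <Track TRACK_ID="0" name="Track_0" NUMBER_SPOTS="3">
        <Edge SPOT_SOURCE_ID="1001" SPOT_TARGET_ID="1002" LINK_COST="0.05" />
        <Edge SPOT_SOURCE_ID="1002" SPOT_TARGET_ID="1003" LINK_COST="0.05" />
      </Track>
      <Track TRACK_ID="1" name="Track_1" NUMBER_SPOTS="3">
        <Edge SPOT_SOURCE_ID="1004" SPOT_TARGET_ID="1005" LINK_COST="0.02" />
        <Edge SPOT_SOURCE_ID="1005" SPOT_TARGET_ID="1006" LINK_COST="0.02" />
      </Track>
    </AllTracks>
    <FilteredTracks>
      <TrackID TRACK_ID="0" />
      <TrackID TRACK_ID="1" />
    </FilteredTracks>
  </Model>
</TrackMate>
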